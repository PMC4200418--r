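#' Read a delimited expression matrix
#'
#' Parses a rows-by-samples table (rows = genes/variables, columns =
#' samples/time points) whose first column holds the row identifiers. Rows
#' containing any missing or non-numeric cell are dropped with a warning; the
#' count of dropped rows is recorded in the `dropped_rows` attribute.
#'
#' @param path File path.
#' @param delimiter Field delimiter (tab by default; use `","` for CSV).
#' @param header Does the first line name the samples?
#' @return An `expression_matrix`: numeric matrix with row names (ids) and
#'   column names (sample ids), >= 4 columns.
#' @export
read_matrix <- function(path, delimiter = "\t", header = TRUE) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  raw <- utils::read.table(path, sep = delimiter, header = header,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 5L) {
    stop("need at least 4 sample columns (plus the id column), got ",
         ncol(raw) - 1L)
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw))
  ok <- apply(vals, 1, function(r) all(is.finite(r)))
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning(dropped, " row(s) with missing/non-numeric cells dropped: ",
            paste(ids[!ok], collapse = ", "))
  }
  m <- vals[ok, , drop = FALSE]
  rownames(m) <- ids[ok]
  colnames(m) <- if (header) names(raw)[-1] else paste0("S", seq_len(ncol(m)))
  attr(m, "dropped_rows") <- dropped
  class(m) <- c("expression_matrix", class(m))
  m
}

# deterministic 31-bit seed from the global seed and a pair of row ids,
# stable across platforms and worker counts
pair_seed <- function(global_seed, id_a, id_b) {
  h <- (global_seed %% 2147483647) + 1
  for (ch in utf8ToInt(paste(id_a, id_b, sep = "\r"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Pairwise MIC over the rows of an expression matrix
#'
#' Computes one edge record per unordered row pair (or per pair in `pairs`),
#' with the chosen engine, a Wilcoxon rank-sum p-value, and a per-pair seed
#' derived deterministically from `seed` and the two row ids — so the output
#' is identical for any `workers` value. Constant rows cannot be ranked and
#' are skipped; their ids are recorded in the `skipped_rows` attribute.
#'
#' @param matrix An [read_matrix()] result, or any numeric matrix with row
#'   names.
#' @param method `"sg"` (default), `"exhaustive"` or `"equiY"`.
#' @param config [ga_config()] for the SG engine.
#' @param alpha Budget exponent.
#' @param seed Global seed from which per-pair seeds are derived.
#' @param workers Number of parallel workers (forked; results do not depend
#'   on this value).
#' @param pairs Optional two-column character matrix/data.frame of row-id
#'   pairs to restrict the computation to.
#' @return `data.frame` of edge records sorted by `(id_a, id_b)` with columns
#'   `id_a`, `id_b`, `mic`, `mi_bits`, `nx`, `ny`, `pvalue`, `method`,
#'   `seed`; `id_a < id_b` lexicographically.
#' @export
pairwise_mic <- function(matrix, method = "sg", config = ga_config(),
                         alpha = 0.6, seed = 1L, workers = 1L,
                         pairs = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  engine <- mic_engine(method)  # validates the tag
  usable <- rownames(matrix)[apply(matrix, 1, function(r) {
    length(unique(r)) > 1L
  })]
  skipped <- setdiff(rownames(matrix), usable)
  if (is.null(pairs)) {
    if (length(usable) < 2L) stop("fewer than 2 usable (non-constant) rows")
    cmb <- utils::combn(sort(usable), 2L)
    pairs <- data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("id_a", "id_b")
    swap <- pairs$id_a > pairs$id_b
    tmp <- pairs$id_a[swap]
    pairs$id_a[swap] <- pairs$id_b[swap]
    pairs$id_b[swap] <- tmp
    missing_ids <- setdiff(unique(c(pairs$id_a, pairs$id_b)),
                           rownames(matrix))
    if (length(missing_ids)) {
      stop("unknown row id(s): ", paste(missing_ids, collapse = ", "))
    }
    pairs <- pairs[pairs$id_a %in% usable & pairs$id_b %in% usable, ,
                   drop = FALSE]
  }
  one_pair <- function(i) {
    id_a <- pairs$id_a[i]
    id_b <- pairs$id_b[i]
    ps <- pair_seed(seed, id_a, id_b)
    s <- paired_sample(matrix[id_a, ], matrix[id_b, ])
    cfg <- config
    cfg$seed <- ps
    res <- switch(method,
      sg = sg_mic(s, alpha, cfg),
      exhaustive = exhaustive_mic(s, alpha),
      equiY = ,
      equiy = equiy_mic(s, alpha)
    )
    data.frame(
      id_a = id_a, id_b = id_b, mic = res$mic, mi_bits = res$mi_bits,
      nx = res$nx, ny = res$ny,
      pvalue = ranksum_pvalue(matrix[id_a, ], matrix[id_b, ]),
      method = res$method, seed = ps, stringsAsFactors = FALSE
    )
  }
  idx <- seq_len(nrow(pairs))
  records <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, one_pair, mc.cores = workers)
  } else {
    lapply(idx, one_pair)
  }
  out <- do.call(rbind, records)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_rows") <- skipped
  out
}

#' Write edge records to TSV
#'
#' Fixed header `id_a id_b mic mi_bits nx ny pvalue method seed` (tab
#' separated), `mic`, `mi_bits` and `pvalue` printed with 6 decimals, rows
#' sorted by `(id_a, id_b)`, LF line endings on every platform.
#'
#' @param records Edge `data.frame` from [pairwise_mic()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_edges <- function(records, path) {
  cols <- c("id_a", "id_b", "mic", "mi_bits", "nx", "ny", "pvalue",
            "method", "seed")
  lines <- paste(cols, collapse = "\t")
  if (nrow(records) > 0) {
    records <- records[order(records$id_a, records$id_b), , drop = FALSE]
    body <- sprintf(
      "%s\t%s\t%.6f\t%.6f\t%d\t%d\t%.6f\t%s\t%d",
      records$id_a, records$id_b, records$mic, records$mi_bits,
      records$nx, records$ny, records$pvalue, records$method,
      as.integer(records$seed)
    )
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read edge records written by [write_edges()]
#'
#' @param path TSV path.
#' @return Edge `data.frame`.
#' @export
read_edges <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Compute MIC for a single pair of vectors
#'
#' Convenience front-end dispatching to the chosen engine.
#'
#' @param xs,ys Paired numeric vectors.
#' @param method `"sg"` (default), `"exhaustive"` or `"equiY"`.
#' @param alpha Budget exponent.
#' @param config [ga_config()] for the SG engine.
#' @return A [mic_result()].
#' @examples
#' mic(1:10, (1:10)^2, method = "sg", config = ga_config(seed = 1))$mic
#' @export
mic <- function(xs, ys, method = "sg", alpha = 0.6, config = ga_config()) {
  s <- paired_sample(xs, ys)
  switch(method,
    sg = sg_mic(s, alpha, config),
    exhaustive = exhaustive_mic(s, alpha),
    equiY = ,
    equiy = equiy_mic(s, alpha),
    stop("unknown method '", method,
         "'; use one of \"sg\", \"exhaustive\", \"equiY\"")
  )
}
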