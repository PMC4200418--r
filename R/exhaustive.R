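#' Decode a bitmask into cut positions
#'
#' The exhaustive engine enumerates axis partitions as integers in
#' `1..(2^(n-1) - 1)`: bit `k` (least significant bit = position 1) decides
#' whether a partition line is inserted between the space-adjacent ranks `k`
#' and `k + 1` (1 means a line, 0 means none). At least one bit is set, so a
#' mask always yields at least two bins.
#'
#' @param value Integer mask in `1..(2^(n-1) - 1)`.
#' @param n Number of data points (`n - 1` candidate cut positions).
#' @return Sorted integer vector of cut positions.
#' @examples
#' mask_to_cuts(1, 5)   # cut {1}
#' mask_to_cuts(5, 5)   # cuts {1, 3}
#' mask_to_cuts(15, 5)  # finest partition {1, 2, 3, 4}
#' @export
mask_to_cuts <- function(value, n) {
  stopifnot(length(value) == 1L, length(n) == 1L, n >= 2)
  value <- as.numeric(value)
  if (value < 1 || value > 2^(n - 1) - 1) {
    stop("mask value must lie in 1..(2^(n-1) - 1) = 1..", 2^(n - 1) - 1)
  }
  bits <- as.integer(intToBits(value))[seq_len(n - 1L)]
  which(bits == 1L)
}

#' MIC by exhaustive enumeration
#'
#' The gold-standard engine: loops over every pair of x- and y-axis cut
#' masks (ascending, x outer and y inner), skips mask pairs whose implied
#' `(nx, ny)` violates the `B(n)` budget without evaluating them, scores the
#' rest, and keeps the maximum (ties broken by the first grid encountered in
#' loop order). Deterministic, and exact by construction — but exponential in
#' `n`, hence guarded by `n_cap`: at 23 points the unpruned loop was observed
#' to take hours, so this engine is a desk-scale oracle, not a production
#' method.
#'
#' @param sample A [paired_sample()].
#' @param alpha Budget exponent, see [bn_threshold()].
#' @param n_cap Refuse samples larger than this (default 18).
#' @return A [mic_result()] with method `"exhaustive"`.
#' @examples
#' s <- paired_sample(1:6, c(2, 4, 6, 8, 10, 12))
#' exhaustive_mic(s)$mic  # 1: perfect monotone dependence
#' @export
exhaustive_mic <- function(sample, alpha = 0.6, n_cap = 18L) {
  ranked <- as_ranked_pairs(sample)
  n <- ranked$n
  if (n > n_cap) {
    stop("n = ", n, " exceeds the exhaustive cap n_cap = ", n_cap,
         "; enumeration is exponential in n. Raise `n_cap` deliberately ",
         "or use sg_mic().")
  }
  budget <- bn_threshold(n, alpha)
  masks <- feasible_masks(n, budget)
  best <- NULL
  evals <- 0L
  for (xi in seq_along(masks$value)) {
    x_cuts <- masks$cuts[[xi]]
    nx <- masks$nbins[xi]
    max_ny <- budget %/% nx
    if (max_ny < 2L) next
    for (yi in seq_along(masks$value)) {
      ny <- masks$nbins[yi]
      if (ny > max_ny) next
      grid <- grid_partition(x_cuts, masks$cuts[[yi]], n)
      res <- score_grid(ranked, grid, method = "exhaustive")
      evals <- evals + 1L
      if (is.null(best) || res$mic > best$mic) best <- res
    }
  }
  best$evaluations <- evals
  best$seed <- NULL
  best
}

# All masks (in ascending mask-value order) whose bin count can participate
# in a feasible shape: nbins = popcount + 1 must satisfy nbins * 2 <= budget.
# Generated by cut-set size rather than by looping over all 2^(n-1) - 1
# integers; the value ordering reproduces the canonical loop order.
feasible_masks <- function(n, budget) {
  max_cuts <- min(budget %/% 2L - 1L, n - 1L)
  cuts <- list()
  for (k in seq_len(max_cuts)) {
    cm <- utils::combn(n - 1L, k)
    cuts <- c(cuts, lapply(seq_len(ncol(cm)), function(i) cm[, i]))
  }
  vals <- vapply(cuts, function(cc) sum(2^(cc - 1)), numeric(1))
  ord <- order(vals)
  list(value = vals[ord], nbins = lengths(cuts)[ord] + 1L, cuts = cuts[ord])
}
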