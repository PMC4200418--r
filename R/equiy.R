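#' Equipartition cut positions
#'
#' Cuts that split `n` ranked points into `k_bins` bins of (near-)equal
#' counts: positions `floor(i * n / k_bins)` for `i = 1..k_bins - 1`,
#' deduplicated. When `n` is not divisible by `k_bins`, the remainder points
#' accumulate in the later bins, so bin counts differ by at most one.
#'
#' @param n Number of points.
#' @param k_bins Number of bins, `2 <= k_bins <= n`.
#' @return Sorted integer vector of cut positions.
#' @examples
#' equipartition_cuts(10, 2)  # 5
#' equipartition_cuts(10, 5)  # 2 4 6 8
#' equipartition_cuts(7, 3)   # 2 4 (bin sizes 2, 2, 3)
#' @export
equipartition_cuts <- function(n, k_bins) {
  stopifnot(k_bins >= 2)
  if (k_bins > n) stop("cannot split ", n, " points into ", k_bins, " bins")
  unique(as.integer(floor(seq_len(k_bins - 1L) * n / k_bins)))
}

#' MIC with the y-axis fixed to an equipartition
#'
#' Baseline engine modeling the failure mode of heuristics that first fix an
#' equipartition of the `n` points with horizontal lines and then optimize
#' only the vertical (x-axis) cuts. For each feasible `ny` it fixes the
#' y-equipartition and maximizes the score over *all* x-cut subsets within
#' the `B(n)` budget (exhaustively, which can only make this baseline
#' stronger than a heuristic x-search), then returns the maximum over `ny`.
#'
#' Because its grids are a strict subset of the full search space,
#' `equiy_mic <= exhaustive_mic` always; on samples whose y-values cluster
#' away from equipartition boundaries the inequality is strict — see
#' [cluster_split_fixture()].
#'
#' @inheritParams exhaustive_mic
#' @return A [mic_result()] with method `"equiY"`.
#' @export
equiy_mic <- function(sample, alpha = 0.6, n_cap = 18L) {
  ranked <- as_ranked_pairs(sample)
  n <- ranked$n
  if (n > n_cap) {
    stop("n = ", n, " exceeds n_cap = ", n_cap,
         " (x-cut subsets are enumerated exhaustively)")
  }
  budget <- bn_threshold(n, alpha)
  best <- NULL
  evals <- 0L
  for (ny in 2:(budget %/% 2L)) {
    y_cuts <- equipartition_cuts(n, ny)
    if (length(y_cuts) != ny - 1L) next  # duplicates collapsed the partition
    max_nx <- budget %/% ny
    if (max_nx < 2L) next
    masks <- feasible_masks(n, 2L * max_nx)  # popcount <= max_nx - 1
    for (xi in seq_along(masks$value)) {
      grid <- grid_partition(masks$cuts[[xi]], y_cuts, n)
      res <- score_grid(ranked, grid, method = "equiY")
      evals <- evals + 1L
      if (is.null(best) || res$mic > best$mic) best <- res
    }
  }
  best$evaluations <- evals
  best
}
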