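#' Grid-size budget B(n)
#'
#' The MIC search is restricted to grids whose bin counts satisfy
#' `nx * ny < B(n)` with `B(n) = n^alpha`; the default exponent is
#' `alpha = 0.6`, calibrated so that statistically independent data receive
#' scores approaching zero as the sample grows while associated data do not.
#' Since `B(n)` is real-valued, the implementation uses the equivalent integer
#' budget `floor(n^alpha)`, with a floor of 4 so that the minimal informative
#' 2-by-2 grid is always admissible (for n <= 10, `n^0.6 < 4` would otherwise
#' forbid every grid and leave MIC undefined for short expression profiles).
#'
#' @param n Number of data points (>= 4).
#' @param alpha Budget exponent in (0, 1).
#' @return Integer budget: the largest admissible value of `nx * ny`.
#' @examples
#' bn_threshold(100)  # 15
#' bn_threshold(23)   # 6
#' bn_threshold(9)    # 4 (fallback floor)
#' @export
bn_threshold <- function(n, alpha = 0.6) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 4)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  max(as.integer(floor(n^alpha)), 4L)
}

#' Enumerate feasible grid shapes
#'
#' All `(nx, ny)` bin-count pairs with `nx, ny >= 2` and
#' `nx * ny <= bn_threshold(n, alpha)`, in lexicographic order. Never empty,
#' thanks to the budget floor of 4.
#'
#' @inheritParams bn_threshold
#' @return Two-column integer matrix with columns `nx`, `ny`, one row per
#'   feasible shape.
#' @examples
#' feasible_shapes(23)  # (2,2), (2,3), (3,2)
#' @export
feasible_shapes <- function(n, alpha = 0.6) {
  budget <- bn_threshold(n, alpha)
  max_nx <- budget %/% 2L
  out <- vector("list", max_nx - 1L)
  for (nx in 2:max_nx) {
    max_ny <- budget %/% nx
    if (max_ny < 2L) next
    out[[nx - 1L]] <- cbind(nx = nx, ny = 2:max_ny)
  }
  shapes <- do.call(rbind, out)
  storage.mode(shapes) <- "integer"
  shapes
}

#' Construct a grid partition of the rank plane
#'
#' A grid is defined by cut positions on each rank axis: a cut at position `k`
#' separates rank `k` from rank `k + 1` (1-based, bins are half-open
#' intervals `(previous cut, cut]` in rank space). With `|x_cuts| = nx - 1`
#' vertical and `|y_cuts| = ny - 1` horizontal cuts the grid has `nx * ny`
#' cells. Because cuts live between ranks, a grid depends only on the order
#' of the data, never on its scale.
#'
#' @param x_cuts,y_cuts Strictly increasing integer vectors of cut positions,
#'   each within `1..(n-1)`; at least one cut per axis.
#' @param n Number of data points.
#' @return An object of class `grid_partition`.
#' @examples
#' grid_partition(x_cuts = 2, y_cuts = 2, n = 4)
#' @export
grid_partition <- function(x_cuts, y_cuts, n) {
  x_cuts <- as.integer(x_cuts)
  y_cuts <- as.integer(y_cuts)
  n <- as.integer(n)
  validate_cuts(x_cuts, n, "x_cuts")
  validate_cuts(y_cuts, n, "y_cuts")
  structure(
    list(x_cuts = x_cuts, y_cuts = y_cuts, n = n),
    class = "grid_partition"
  )
}

validate_cuts <- function(cuts, n, what) {
  if (length(cuts) < 1L) {
    stop("`", what, "` must contain at least one cut (two bins)")
  }
  if (any(cuts < 1L) || any(cuts > n - 1L)) {
    stop("`", what, "` positions must lie in 1..(n-1)")
  }
  if (any(diff(cuts) <= 0L)) {
    stop("`", what, "` positions must be strictly increasing")
  }
  invisible(cuts)
}

#' @export
print.grid_partition <- function(x, ...) {
  cat("<grid_partition> ", length(x$x_cuts) + 1L, "x", length(x$y_cuts) + 1L,
      " grid on n = ", x$n, " ranks\n", sep = "")
  cat("  x cuts:", x$x_cuts, "\n  y cuts:", x$y_cuts, "\n")
  invisible(x)
}

# bin index of each rank for a sorted cut vector: 1 + #{cuts < r}
bin_index <- function(ranks, cuts) {
  findInterval(ranks - 1L, cuts) + 1L
}

#' Contingency table of a grid partition
#'
#' Counts the points falling into each grid cell: cell `(i, j)` holds the
#' number of points whose x-rank lies in x-bin `i` and y-rank in y-bin `j`.
#' The cell total always equals `n`.
#'
#' @param ranked A [rank_transform()] result (or a `paired_sample`, which is
#'   ranked on the fly).
#' @param grid A [grid_partition()].
#' @return Integer matrix with `nx` rows and `ny` columns.
#' @export
contingency_table <- function(ranked, grid) {
  ranked <- as_ranked_pairs(ranked)
  stopifnot(inherits(grid, "grid_partition"), grid$n == ranked$n)
  nx <- length(grid$x_cuts) + 1L
  ny <- length(grid$y_cuts) + 1L
  xb <- bin_index(ranked$xr, grid$x_cuts)
  yb <- bin_index(ranked$yr, grid$y_cuts)
  counts <- tabulate((yb - 1L) * nx + xb, nbins = nx * ny)
  matrix(as.integer(counts), nrow = nx, ncol = ny)
}

#' Empirical mutual information of a contingency table (bits)
#'
#' `I = sum_ij p_ij log2(p_ij / (p_i. p_.j))` with the usual convention
#' `0 * log 0 = 0`, where `p_ij` are cell frequencies. Always non-negative
#' and bounded above by `log2(min(nx, ny))`.
#'
#' @param counts Non-negative integer matrix of cell counts (sum >= 1).
#' @return Mutual information in bits.
#' @examples
#' mutual_information(matrix(c(5, 0, 0, 5), 2))  # 1 bit
#' mutual_information(matrix(c(2, 2, 2, 2), 2))  # 0 bits
#' @export
mutual_information <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  n <- sum(counts)
  if (n < 1) stop("cell counts must sum to at least 1")
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  nz <- which(p > 0)
  i <- ((nz - 1L) %% nrow(p)) + 1L
  j <- ((nz - 1L) %/% nrow(p)) + 1L
  mi <- sum(p[nz] * log2(p[nz] / (px[i] * py[j])))
  max(mi, 0)
}

#' Normalize mutual information to the MIC scale
#'
#' Divides the mutual information by `log2(min(nx, ny))`, the maximum it can
#' attain on an `nx`-by-`ny` grid, giving a score in `[0, 1]`. Clamping is
#' applied only against floating-point error (never by more than `1e-9`).
#'
#' @param mi_bits Mutual information in bits (>= 0).
#' @param nx,ny Bin counts of the grid (each >= 2).
#' @return Normalized score in `[0, 1]`.
#' @examples
#' normalized_score(1, 2, 2)    # 1
#' normalized_score(1.2, 3, 4)  # 1.2 / log2(3)
#' @export
normalized_score <- function(mi_bits, nx, ny) {
  stopifnot(nx >= 2, ny >= 2, mi_bits >= 0)
  s <- mi_bits / log2(min(nx, ny))
  if (s > 1) {
    if (s > 1 + 1e-9) {
      stop("normalized score exceeds 1 beyond floating tolerance: ", s)
    }
    s <- 1
  }
  s
}

#' Score one grid on one ranked sample
#'
#' Composes [contingency_table()], [mutual_information()] and
#' [normalized_score()] into a [mic_result()] for a single, explicitly given
#' grid. This is the fitness function every search engine maximizes.
#'
#' @inheritParams contingency_table
#' @param method Tag recorded in the result (default `"manual"`).
#' @return A [mic_result()].
#' @export
score_grid <- function(ranked, grid, method = "manual") {
  ranked <- as_ranked_pairs(ranked)
  counts <- contingency_table(ranked, grid)
  mi <- mutual_information(counts)
  nx <- nrow(counts)
  ny <- ncol(counts)
  mic_result(
    mic = normalized_score(mi, nx, ny),
    mi_bits = mi, nx = nx, ny = ny, grid = grid,
    method = method, evaluations = 1L, generations = 0L, seed = NULL
  )
}

#' MIC result container
#'
#' The common return type of all engines: the MIC value, the grid achieving
#' it, the raw mutual information, the grid shape, a method tag, and search
#' diagnostics.
#'
#' @param mic MIC value in `[0, 1]`.
#' @param mi_bits Mutual information of the achieving grid, in bits.
#' @param nx,ny Bin counts of the achieving grid.
#' @param grid The achieving [grid_partition()].
#' @param method One of `"sg"`, `"exhaustive"`, `"equiY"`, `"manual"`.
#' @param evaluations Number of grid evaluations performed.
#' @param generations Number of GA generations run (0 for non-iterative
#'   methods).
#' @param seed Seed used, or `NULL`.
#' @param diagnostics Optional list of engine-specific diagnostics.
#' @return An object of class `mic_result`.
#' @export
mic_result <- function(mic, mi_bits, nx, ny, grid, method,
                       evaluations = NA_integer_, generations = 0L,
                       seed = NULL, diagnostics = NULL) {
  stopifnot(mic >= 0, mic <= 1, mi_bits >= 0)
  structure(
    list(
      mic = mic, mi_bits = mi_bits, nx = as.integer(nx), ny = as.integer(ny),
      grid = grid, method = method, evaluations = as.integer(evaluations),
      generations = as.integer(generations), seed = seed,
      diagnostics = diagnostics
    ),
    class = "mic_result"
  )
}

#' @export
print.mic_result <- function(x, ...) {
  cat(sprintf("<mic_result> MIC = %.6f (%s)\n", x$mic, x$method))
  cat(sprintf("  grid: %d x %d, I = %.6f bits\n", x$nx, x$ny, x$mi_bits))
  cat(sprintf("  evaluations: %d, generations: %d\n",
              x$evaluations, x$generations))
  invisible(x)
}
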