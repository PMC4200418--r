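test_that("rank transform produces order-preserving permutations", {
  r <- rank_transform(paired_sample(c(3.2, 1.1, 5.0, 2.0), c(10, 40, 20, 30)))
  expect_identical(r$xr, c(3L, 1L, 4L, 2L))
  expect_identical(r$yr, c(1L, 4L, 2L, 3L))

  # ties broken by original index: stable
  r <- rank_transform(paired_sample(c(1, 1, 2, 3), c(4, 3, 2, 1)))
  expect_identical(r$xr, c(1L, 2L, 3L, 4L))

  # identity fixed point
  r <- rank_transform(paired_sample(1:7, 7:1))
  expect_identical(r$xr, 1:7)
  expect_identical(r$yr, 7:1)

  for (sd in 1:10) {
    set.seed(sd)
    r <- rank_transform(paired_sample(rnorm(12), rnorm(12)))
    expect_identical(sort(r$xr), 1:12)
    expect_identical(sort(r$yr), 1:12)
  }
})

test_that("degenerate and invalid samples are rejected", {
  expect_error(rank_transform(paired_sample(rep(1, 5), 1:5)), "constant")
  expect_error(rank_transform(paired_sample(1:5, rep(2, 5))), "constant")
  expect_error(paired_sample(c(1, NA, 3, 4), 1:4), "finite")
  expect_error(paired_sample(c(1, Inf, 3, 4), 1:4), "finite")
  expect_error(paired_sample(1:3, 1:3), "at least 4")
  expect_error(paired_sample(1:5, 1:4), "same length")
})

test_that("grid-size budget follows floor(n^alpha) with a floor of 4", {
  expect_identical(bn_threshold(100), 15L)
  expect_identical(bn_threshold(23), 6L)
  expect_identical(bn_threshold(9), 4L)   # 9^0.6 < 4: fallback
  expect_identical(bn_threshold(4), 4L)
  expect_identical(bn_threshold(100, alpha = 0.95), 79L)
  expect_error(bn_threshold(3))
  expect_error(bn_threshold(100, alpha = 1))
})

test_that("feasible shapes match an independent enumeration", {
  expect_identical(
    feasible_shapes(23),
    matrix(c(2L, 2L, 2L, 3L, 3L, 2L), ncol = 2, byrow = TRUE,
           dimnames = list(NULL, c("nx", "ny")))
  )
  expect_identical(nrow(feasible_shapes(9)), 1L)  # only (2,2)

  for (n in c(9, 23, 100, 200)) {
    budget <- bn_threshold(n)
    oracle <- expand.grid(nx = 2:budget, ny = 2:budget)
    oracle <- oracle[oracle$nx * oracle$ny <= budget, ]
    oracle <- oracle[order(oracle$nx, oracle$ny), ]
    got <- feasible_shapes(n)
    expect_identical(nrow(got), nrow(oracle))
    expect_identical(unname(got[, "nx"]), as.integer(oracle$nx))
    expect_identical(unname(got[, "ny"]), as.integer(oracle$ny))
  }
})

test_that("contingency counts conserve n and place points correctly", {
  r <- list(xr = 1:4, yr = 1:4, n = 4L)
  class(r) <- "ranked_pairs"
  g <- grid_partition(2, 2, 4)
  expect_identical(contingency_table(r, g),
                   matrix(c(2L, 0L, 0L, 2L), 2))

  r$yr <- 4:1
  expect_identical(contingency_table(r, g),
                   matrix(c(0L, 2L, 2L, 0L), 2))

  # conservation on arbitrary grids
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    rp <- rank_transform(paired_sample(rnorm(n), rnorm(n)))
    xc <- sort(sample(n - 1, sample(3, 1)))
    yc <- sort(sample(n - 1, sample(3, 1)))
    tab <- contingency_table(rp, grid_partition(xc, yc, n))
    expect_identical(sum(tab), n)
    expect_true(all(tab >= 0))
  }
})

test_that("mutual information matches hand computations", {
  expect_equal(mutual_information(matrix(c(5, 0, 0, 5), 2)), 1.0)
  expect_equal(mutual_information(matrix(c(2, 2, 2, 2), 2)), 0.0)
  # H(X) + H(Y) - H(X,Y) = 1 + 1 - 1.72193 for [[4,1],[1,4]]
  h_joint <- -2 * (0.4 * log2(0.4) + 0.1 * log2(0.1))
  expect_equal(mutual_information(matrix(c(4, 1, 1, 4), 2)), 2 - h_joint,
               tolerance = 1e-12)
  expect_error(mutual_information(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("normalized score divides by log2(min shape) and clamps safely", {
  expect_equal(normalized_score(1, 2, 2), 1)
  expect_equal(normalized_score(0, 5, 3), 0)
  expect_equal(normalized_score(1.2, 3, 4), 1.2 / log2(3), tolerance = 1e-12)
  expect_equal(normalized_score(1 + 1e-12, 2, 2), 1)  # fp guard
  expect_error(normalized_score(1.1, 2, 2), "tolerance")
})

test_that("score_grid composes correctly on a worked 6-point example", {
  r <- rank_transform(paired_sample(1:6, c(3, 1, 2, 6, 4, 5)))
  res <- score_grid(r, grid_partition(3, 2, 6))
  # contingency [[2,1],[0,3]]: I = H(2/6) + H(3/6,1/6,...) hand-computed
  px <- c(3, 3) / 6
  py <- c(2, 4) / 6
  pxy <- c(2, 0, 1, 3) / 6
  ent <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(res$mi_bits, ent(px) + ent(py) - ent(pxy), tolerance = 1e-12)
  expect_equal(res$mic, res$mi_bits / log2(2))
  expect_equal(res$mic, 0.459147917027245, tolerance = 1e-12)

  # perfect monotone dependence, balanced 2x2
  mono <- rank_transform(paired_sample(1:8, (1:8)^2))
  expect_equal(score_grid(mono, grid_partition(4, 4, 8))$mic, 1.0)
  # exact independence table
  r <- list(xr = 1:4, yr = c(3L, 1L, 4L, 2L), n = 4L)
  class(r) <- "ranked_pairs"
  expect_equal(score_grid(r, grid_partition(2, 2, 4))$mic, 0.0)
})

test_that("MIC is invariant under monotone transforms and x/y swap", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(10)
    y <- runif(10)
    rp <- rank_transform(paired_sample(x, y))
    rp_t <- rank_transform(paired_sample(exp(2 * x), y^3))
    xc <- sort(sample(9, 2))
    yc <- sort(sample(9, 1))
    g <- grid_partition(xc, yc, 10)
    expect_identical(rp$xr, rp_t$xr)
    expect_equal(score_grid(rp, g)$mic, score_grid(rp_t, g)$mic)

    # swapping axes (and cut roles) leaves MI unchanged
    rp_sw <- list(xr = rp$yr, yr = rp$xr, n = rp$n)
    class(rp_sw) <- "ranked_pairs"
    g_sw <- grid_partition(yc, xc, 10)
    expect_equal(score_grid(rp, g)$mi_bits, score_grid(rp_sw, g_sw)$mi_bits,
                 tolerance = 1e-12)
  }
})

test_that("compiled scorer agrees with the R scorer on random grids", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    rp <- rank_transform(paired_sample(rnorm(n), rnorm(n)))
    xc <- sort(sample(n - 1, sample(4, 1)))
    yc <- sort(sample(n - 1, sample(4, 1)))
    r_val <- score_grid(rp, grid_partition(xc, yc, n))$mic
    c_val <- micsg:::mic_score_cpp(rp$xr, rp$yr, xc, yc)
    expect_equal(c_val, r_val, tolerance = 1e-12)
  }
})

test_that("mic_result enforces its invariants", {
  g <- grid_partition(2, 2, 4)
  res <- mic_result(0.5, 0.5, 2, 2, g, "manual")
  expect_s3_class(res, "mic_result")
  expect_equal(res$mic, res$mi_bits / log2(min(res$nx, res$ny)))
  expect_error(mic_result(1.5, 1.5, 2, 2, g, "manual"))
  expect_output(print(res), "MIC = 0.5")
})
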