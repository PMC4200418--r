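test_that("GA configuration validates its constraints", {
  cfg <- ga_config()
  expect_identical(cfg$population_size, 20L)
  expect_identical(cfg$stall_limit, 30L)
  expect_error(ga_config(pm1 = 0.01, pm2 = 0.1))   # needs pm1 > pm2
  expect_error(ga_config(pc1 = 0.5, pc2 = 0.6))
  expect_error(ga_config(population_size = 1))
  expect_error(ga_config(cooling = 1))
})

test_that("population-size schedule follows the published brackets", {
  expect_identical(population_size_for(23), 20L)
  expect_identical(population_size_for(30), 20L)
  expect_identical(population_size_for(40), 100L)
  expect_identical(population_size_for(75), 1000L)
  expect_identical(population_size_for(150), 10000L)
  expect_warning(expect_identical(population_size_for(300), 100000L),
                 "runtime")
})

test_that("population initialization is shaped, valid and seed-deterministic", {
  rp <- rank_transform(random_cloud(23, seed = 4))
  set.seed(1)
  pop <- init_population(rp, c(2, 3), ga_config())
  expect_length(pop, 20)
  for (ch in pop) {
    expect_length(ch$xgenes, 1)
    expect_length(ch$ygenes, 2)
    expect_true(all(ch$ygenes %in% 1:22))
    expect_true(all(diff(ch$ygenes) > 0))
    expect_false(is.na(ch$fitness))
  }
  set.seed(1)
  pop2 <- init_population(rp, c(2, 3), ga_config())
  expect_identical(pop, pop2)
  expect_error(init_population(rp, c(4, 4), ga_config()), "infeasible")
})

test_that("self-adaptive rate interpolates between pm1 and pm2", {
  expect_equal(adaptive_mutation_prob(0.9, 0.9, 0.5, 0.1, 0.01), 0.01)
  expect_equal(adaptive_mutation_prob(0.4, 0.9, 0.5, 0.1, 0.01), 0.1)
  expect_equal(adaptive_mutation_prob(0.5, 0.5, 0.5, 0.1, 0.01), 0.1)
  expect_equal(adaptive_mutation_prob(0.7, 0.9, 0.5, 0.1, 0.01),
               0.1 - 0.09 * 0.2 / 0.4)
  for (f in seq(0, 1, by = 0.1)) {
    p <- adaptive_mutation_prob(f, 1, 0.4, 0.1, 0.01)
    expect_gte(p, 0.01)
    expect_lte(p, 0.1)
  }
})

test_that("mutation moves one line per axis within its neighbor bounds", {
  rp <- rank_transform(random_cloud(10, seed = 2))
  # interior gene with neighbors 2 and 4 can only be 3
  set.seed(5)
  for (rep in 1:40) {
    ch <- micsg:::new_chromosome(c(2, 3, 4), 5, fitness = 0)
    m <- mutate_chromosome(ch, rp)
    # one gene moved per axis: the interior gene is wedged at 3 whichever
    # neighbor moves; the first stays in [1, 2], the last in [4, 9]
    expect_identical(m$xgenes[2], 3L)
    expect_true(m$xgenes[1] %in% 1:2)
    expect_true(m$xgenes[3] %in% 4:9)
    expect_lte(sum(m$xgenes != c(2L, 3L, 4L)), 1L)
    # lone y-gene may land anywhere in 1..9
    expect_true(m$ygenes %in% 1:9)
    expect_length(m$ygenes, 1)
  }
  # validity preserved on random chromosomes
  set.seed(6)
  for (rep in 1:50) {
    xg <- sort(sample(9, 3))
    yg <- sort(sample(9, 2))
    m <- mutate_chromosome(micsg:::new_chromosome(xg, yg, 0), rp)
    expect_length(m$xgenes, 3)
    expect_length(m$ygenes, 2)
    expect_true(all(diff(m$xgenes) > 0) && all(diff(m$ygenes) > 0))
    expect_true(all(c(m$xgenes, m$ygenes) %in% 1:9))
  }
})

test_that("conditional mutation fires at the requested empirical rate", {
  rp <- rank_transform(random_cloud(8, seed = 3))
  ch <- micsg:::new_chromosome(4, 4, fitness = 0)
  set.seed(9)
  hits <- 0L
  for (i in 1:10000) {
    m <- maybe_mutate(ch, rp, 0.3)
    hits <- hits + !identical(m[c("xgenes", "ygenes")],
                              ch[c("xgenes", "ygenes")])
  }
  # a mutated lone gene resamples its own position with prob 1/49, so the
  # observable change rate is 0.3 * 48/49
  rate <- hits / 10000
  expect_gt(rate, 0.27)
  expect_lt(rate, 0.32)
  # degenerate rates
  set.seed(1)
  expect_identical(maybe_mutate(ch, rp, 0), ch)
})

test_that("same-axis crossover preserves shape and validity", {
  rp <- rank_transform(random_cloud(12, seed = 8))
  set.seed(10)
  p1 <- micsg:::new_chromosome(c(2, 5, 8), c(3, 9), 0.1)
  p2 <- micsg:::new_chromosome(c(1, 6, 10), c(4, 7), 0.2)
  for (rep in 1:40) {
    kids <- crossover_chromosomes(p1, p2, rp, pc = 1)
    for (k in kids) {
      expect_length(k$xgenes, 3)
      expect_length(k$ygenes, 2)
      expect_true(all(diff(k$xgenes) > 0) && all(diff(k$ygenes) > 0))
      expect_true(all(c(k$xgenes, k$ygenes) %in% 1:11))
      expect_false(is.na(k$fitness))
    }
  }
  # pc = 0: children are copies
  kids <- crossover_chromosomes(p1, p2, rp, pc = 0)
  expect_identical(kids[[1]], p1)
  expect_identical(kids[[2]], p2)
  # identical parents produce identical children
  kids <- crossover_chromosomes(p1, p1, rp, pc = 1)
  expect_identical(kids[[1]]$xgenes, p1$xgenes)
  expect_identical(kids[[2]]$ygenes, p1$ygenes)
  expect_error(crossover_chromosomes(
    p1, micsg:::new_chromosome(c(2, 5), c(3, 9), 0), rp, 1), "shape")
})

test_that("proportional selection concentrates on fitness and degrades safely", {
  set.seed(12)
  # single non-zero fitness: every draw hits it
  expect_true(all(select_proportional(c(0, 1, 0, 0)) == 2L))
  # all-zero: uniform fallback, no division error
  idx <- select_proportional(rep(0, 5))
  expect_length(idx, 5)
  expect_true(all(idx %in% 1:5))
  # equal fitness: empirical frequencies uniform within 3 sigma
  counts <- integer(4)
  for (i in 1:2500) {
    idx <- select_proportional(rep(0.5, 4))
    counts <- counts + tabulate(idx, 4)
  }
  expected <- 2500 * 4 / 4
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - expected) < 3 * sigma))
})

test_that("Metropolis acceptance matches its closed form", {
  expect_true(metropolis_accept(0.1, 0.05))
  expect_true(metropolis_accept(0, 1e-6))
  set.seed(13)
  expect_false(any(replicate(200, metropolis_accept(-10, 0.01))))
  acc <- mean(replicate(10000, metropolis_accept(-0.05, 0.05)))
  expect_equal(acc, exp(-1), tolerance = 0.04)
})

test_that("sg_mic finds the exact optimum on monotone data and is deterministic", {
  s <- paired_sample(1:20, log(1:20))
  r1 <- sg_mic(s, config = ga_config(seed = 42))
  expect_identical(r1$mic, 1.0)
  expect_identical(r1$method, "sg")
  r2 <- sg_mic(s, config = ga_config(seed = 42))
  expect_identical(r1$mic, r2$mic)
  expect_identical(r1$grid$x_cuts, r2$grid$x_cuts)
  expect_identical(r1$evaluations, r2$evaluations)
  expect_identical(r1$diagnostics$best_by_generation,
                   r2$diagnostics$best_by_generation)
})

test_that("champion fitness is non-decreasing and bounded by the oracle", {
  for (sd in 1:10) {
    s <- random_cloud(8, seed = sd)
    res <- sg_mic(s, config = ga_config(seed = sd))
    expect_true(all(diff(res$diagnostics$best_by_generation) >= 0))
    expect_lte(res$mic, exhaustive_mic(s)$mic + 1e-12)
    expect_equal(res$mic,
                 res$mi_bits / log2(min(res$nx, res$ny)), tolerance = 1e-12)
  }
})

test_that("reference engine mirrors the compiled engine's behavior", {
  s <- paired_sample(1:12, (1:12)^2)
  ref <- sg_mic(s, config = ga_config(seed = 5, engine = "reference"))
  cpp <- sg_mic(s, config = ga_config(seed = 5, engine = "compiled"))
  expect_identical(ref$mic, 1.0)
  expect_identical(cpp$mic, 1.0)

  # both respect the exhaustive bound and usually attain it at n = 8
  hits_ref <- 0L
  for (sd in 1:5) {
    s <- random_cloud(8, seed = 100 + sd)
    ex <- exhaustive_mic(s)$mic
    rv <- sg_mic(s, config = ga_config(seed = sd, engine = "reference"))$mic
    expect_lte(rv, ex + 1e-12)
    hits_ref <- hits_ref + (abs(rv - ex) < 1e-12)
  }
  expect_gte(hits_ref, 4L)
})
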