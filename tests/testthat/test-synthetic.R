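test_that("the registry holds 14 families and rejects unknown ones", {
  fams <- relationship_families()
  expect_length(fams, 14)
  expect_true(all(c("sine", "tangent", "power", "exponential", "inverse",
                    "composite", "taijitu", "galaxy", "heart", "polygon",
                    "circle", "ellipse", "cross", "two_lines") %in% fams))
  expect_error(generate_relationship("spiral_of_doom", 0, 100, 1),
               "registered families")
})

test_that("noiseless function families satisfy their law exactly", {
  s <- generate_relationship("power", noise_level = 0, n = 100, seed = 1)
  expect_equal(s$ys, s$xs^2)
  s <- generate_relationship("exponential", 0, 50, 2)
  expect_equal(s$ys, 10^s$xs)
  s <- generate_relationship("inverse", 0, 50, 3)
  expect_equal(s$ys, 1 / s$xs)
  s <- generate_relationship("sine", 0, 50, 4)
  expect_equal(s$ys, sin(s$xs))
})

test_that("generation is deterministic per seed and varies across seeds", {
  a <- generate_relationship("taijitu", 2, 200, seed = 7)
  b <- generate_relationship("taijitu", 2, 200, seed = 7)
  c <- generate_relationship("taijitu", 2, 200, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$xs, c$xs))
})

test_that("noise amplitude grades are strictly increasing", {
  expect_true(all(diff(micsg:::noise_sigma_levels) > 0))
  # observable consequence: departure from the noiseless curve grows
  clean <- generate_relationship("power", 0, 500, seed = 5)
  dev <- sapply(1:3, function(lvl) {
    s <- generate_relationship("power", lvl, 500, seed = 5)
    sd(s$ys - s$xs^2)
  })
  expect_true(all(diff(dev) > 0))
})

test_that("random clouds are uniform, reproducible and weakly correlated", {
  s <- random_cloud(100, seed = 1)
  expect_identical(s, random_cloud(100, seed = 1))
  expect_false(identical(s$xs, random_cloud(100, seed = 2)$xs))
  expect_true(all(s$xs > 0 & s$xs < 1 & s$ys > 0 & s$ys < 1))
  rho <- sapply(1:40, function(sd) {
    s <- random_cloud(100, seed = sd)
    abs(cor(rank(s$xs), rank(s$ys)))
  })
  expect_gte(mean(rho < 0.3), 0.95)
})

test_that("the full suite covers 14 families x 4 noise levels", {
  suite <- relationship_suite(n = 50, seed = 3)
  expect_length(suite, 56)
  key <- sapply(suite, function(e) paste(e$family, e$noise_level))
  expect_identical(anyDuplicated(key), 0L)
  expect_identical(anyDuplicated(sapply(suite, `[[`, "seed")), 0L)
  # noise level 0 entries are exactly on-curve for a function family
  pow0 <- Filter(function(e) e$family == "power" && e$noise_level == 0, suite)
  expect_equal(pow0[[1]]$sample$ys, pow0[[1]]$sample$xs^2)
  for (e in suite) expect_identical(e$sample$n, 50L)
})
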