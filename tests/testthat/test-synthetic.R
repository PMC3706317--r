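test_that("make_climate is deterministic and obeys its gradient structure", {
  meta <- grid_meta(30, 40)
  c1 <- make_climate(meta, seed = 7)
  c2 <- make_climate(meta, seed = 7)
  expect_identical(c1$t_cold, c2$t_cold)
  expect_identical(c1$gdd5, c2$gdd5)
  expect_identical(c1$moisture, c2$moisture)
  expect_identical(c1$mask, c2$mask)
  c3 <- make_climate(meta, seed = 8)
  expect_false(identical(c1$t_cold, c3$t_cold))

  # north (row 1) colder than south (last row)
  expect_lt(mean(c1$t_cold[1, ]), mean(c1$t_cold[30, ]))
  expect_true(all(c1$gdd5 >= 0))
  expect_true(all(c1$moisture >= 0 & c1$moisture <= 1))
  expect_equal(mean(!c1$mask), 0.25, tolerance = 0.05)
})

test_that("zero noise amplitude gives exactly linear gradients", {
  meta <- grid_meta(10, 10)
  cl <- make_climate(meta, seed = 1, params = list(
    t_cold_noise_sd = 0, gdd5_noise_sd = 0, moisture_noise_sd = 0,
    sea_fraction = 0
  ))
  # columns of t_cold identical; rows of moisture identical
  expect_equal(cl$t_cold, matrix(cl$t_cold[, 1], 10, 10))
  expect_equal(cl$moisture, matrix(cl$moisture[1, ], 10, 10, byrow = TRUE))
  expect_equal(cl$t_cold[1, 1], -22)
  expect_equal(cl$t_cold[10, 1], 8)
  expect_true(all(diff(cl$t_cold[, 1]) > 0))
  expect_true(all(cl$mask))
})

test_that("envelope_model applies hard limits and trapezoidal ramps", {
  meta <- grid_meta(10, 10)
  cl <- make_climate(meta, seed = 2, params = list(sea_fraction = 0))
  lim <- toy_species_limits(
    gdd5min_e = 900, t_cold_min_s = -17, t_cold_min_e = -14,
    t_cold_max_e = 6, moisture_min = 0.3
  )
  env <- envelope_model(cl, lim)
  v <- env$values
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(v[cl$t_cold < lim$t_cold_min_s] == 0))
  expect_true(all(v[cl$gdd5 < lim$gdd5min_e] == 0))
  expect_true(all(v[cl$moisture < lim$moisture_min] == 0))

  # direct trapezoid arithmetic: halfway up one ramp, core elsewhere
  cl2 <- cl
  cl2$t_cold[] <- lim$t_cold_min_s + 2 # halfway up a 4-degree ramp
  cl2$gdd5[] <- 3000
  cl2$moisture[] <- 0.8
  v2 <- envelope_model(cl2, lim)$values
  expect_equal(unique(as.vector(v2)), 0.5)
  cl2$t_cold[] <- 0 # core of every response
  expect_equal(unique(as.vector(envelope_model(cl2, lim)$values)), 1)
})

test_that("toy_species_limits enforces the limit ordering", {
  expect_error(toy_species_limits(t_cold_min_s = -10, t_cold_min_e = -12), "restrictive")
  expect_error(toy_species_limits(t_cold_min_e = -5, t_cold_max_e = -5), "exceed")
})

test_that("hybrid_model nests establishment within survival within growth", {
  meta <- grid_meta(20, 24)
  set.seed(51)
  for (i in 1:100) {
    cl <- make_climate(meta, seed = 1000 + i)
    t_min_s <- runif(1, -35, -5)
    t_min_e <- t_min_s + runif(1, 0, 8)
    lim <- toy_species_limits(
      gdd5min_e = runif(1, 300, 2500),
      t_cold_min_s = t_min_s,
      t_cold_min_e = t_min_e,
      t_cold_max_e = t_min_e + runif(1, 2, 25),
      moisture_min = runif(1, 0.1, 0.6)
    )
    h <- hybrid_model(cl, lim)
    g <- h$growth$values[cl$mask] > 0
    s <- h$survival_zone$values[cl$mask] == 1
    e <- h$establishment_zone$values[cl$mask] == 1
    expect_true(all(s <= g)) # survival subset of positive growth
    expect_true(all(e <= s)) # establishment subset of survival
  }
})

test_that("hybrid_model flag and limit-ordering semantics", {
  meta <- grid_meta(15, 15)
  cl <- make_climate(meta, seed = 52, params = list(sea_fraction = 0))
  lim <- toy_species_limits()
  free <- hybrid_model(cl, lim, apply_bioclim_limits = FALSE)
  expect_equal(free$lai$values, free$growth$values)
  gated <- hybrid_model(cl, lim, apply_bioclim_limits = TRUE)
  ez <- gated$establishment_zone$values == 1
  expect_true(all(gated$lai$values[!ez] == 0))
  expect_equal(gated$lai$values[ez], gated$growth$values[ez])

  # a cell between the survival and establishment cold limits is in the
  # survival zone but not the establishment zone (given growth there)
  cl$t_cold[] <- (lim$t_cold_min_s + lim$t_cold_min_e) / 2
  cl$gdd5[] <- 4000
  cl$moisture[] <- 0.8
  h <- hybrid_model(cl, lim)
  expect_true(all(h$survival_zone$values == 1))
  expect_true(all(h$establishment_zone$values == 0))
})

test_that("fitness_model is the product of survival and reproduction", {
  cl <- make_climate(grid_meta(12, 12), seed = 53)
  f <- fitness_model(cl)
  expect_equal(
    f$fitness$values[cl$mask],
    f$survival_p$values[cl$mask] * f$reproduction_p$values[cl$mask]
  )
  expect_true(all(f$fitness$values[cl$mask] >= 0 &
    f$fitness$values[cl$mask] <= 1))
})

test_that("observed_distribution thresholds, flips and is seed-deterministic", {
  s <- standardize(rand_score(15, 15, seed = 54))
  o0 <- observed_distribution(s, 0.5, flip_noise = 0, seed = 1)
  expect_equal(o0$values, matrix(as.numeric(s$values >= 0.5), 15, 15))
  o1 <- observed_distribution(s, 0.5, flip_noise = 1, seed = 1)
  expect_equal(o1$values, 1 - o0$values)
  oa <- observed_distribution(s, 0.5, flip_noise = 0.3, seed = 9)
  ob <- observed_distribution(s, 0.5, flip_noise = 0.3, seed = 9)
  expect_identical(oa$values, ob$values)
  expect_error(observed_distribution(s, 0.5, flip_noise = 1.2), "probability")
})

test_that("random_binary_map draws Bernoulli(p) per valid cell", {
  meta <- grid_meta(200, 200)
  expect_true(all(random_binary_map(meta, 0, seed = 1)$values == 0))
  expect_true(all(random_binary_map(meta, 1, seed = 1)$values == 1))
  m <- random_binary_map(meta, 0.5, seed = 2)
  expect_equal(mean(m$values), 0.5, tolerance = 0.04) # 8 sigma of binomial se
  m2 <- random_binary_map(meta, 0.5, seed = 2)
  expect_identical(m$values, m2$values)
  # generators leave the global RNG state alone
  set.seed(99)
  before <- .Random.seed
  invisible(random_binary_map(grid_meta(5, 5), 0.5, seed = 3))
  expect_identical(.Random.seed, before)
})
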