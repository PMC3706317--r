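test_that("window_offsets builds the Euclidean disc", {
  expect_equal(nrow(window_offsets(0)$offsets), 1)
  expect_equal(nrow(window_offsets(1)$offsets), 5)
  expect_equal(nrow(window_offsets(2)$offsets), 13)
  off <- window_offsets(3)$offsets
  expect_true(all(off[, 1]^2 + off[, 2]^2 <= 9))
  # symmetric under negation, contains the centre
  expect_true(any(off[, 1] == 0 & off[, 2] == 0))
  neg <- -off
  expect_setequal(paste(off[, 1], off[, 2]), paste(neg[, 1], neg[, 2]))
  expect_error(window_offsets(-1), "non-negative")
})

test_that("scale-1 window spans 0.5 degrees on a 10-arcminute grid", {
  expect_equal(window_span_degrees(1, cell_size = 1 / 6), 0.5)
})

test_that("self- and anti-comparison give the identity values", {
  set.seed(31)
  a <- rand_binary(9, 9, 0.5)
  anti <- binary_map(a$meta, 1 - a$values, a$mask)
  k_self <- monoscale_kappa(a, a, 2)
  expect_true(all(k_self$values[k_self$mask] == 1))
  # complement maps: strictly negative kappa wherever a window holds both
  # classes (and exactly -1 when the window is class-balanced), 0 where the
  # window is single-class in both maps
  k_anti <- monoscale_kappa(a, anti, 2)
  inner <- k_anti$values[3:7, 3:7]
  expect_true(all(inner >= -1 & inner <= 0))
  expect_true(any(inner < 0))
  balanced <- binary_map(
    grid_meta(1, 10), matrix(rep(c(0, 1), 5), 1)
  )
  flipped <- binary_map(balanced$meta, 1 - balanced$values)
  expect_equal(
    cohen_kappa(confusion(balanced, flipped)), -1
  )

  s <- rand_score(9, 9, seed = 32)
  d_self <- monoscale_distance(s, s, 2)
  expect_true(all(d_self$values[d_self$mask] == 0))
  comp <- score_map(s$meta, 1 - s$values, s$mask)
  ones <- score_map(s$meta, matrix(1, 9, 9))
  zeros <- score_map(s$meta, matrix(0, 9, 9))
  d10 <- monoscale_distance(ones, zeros, 2)
  expect_true(all(d10$values[d10$mask] == 1))

  cc_self <- monoscale_cc(s, s, 2)
  expect_true(all(abs(cc_self$values[cc_self$mask] - 1) < 1e-12))
  cc_anti <- monoscale_cc(s, comp, 2)
  expect_true(all(abs(cc_anti$values[cc_anti$mask] + 1) < 1e-12))
})

test_that("a constant window makes CC undefined at that centre", {
  v <- matrix(runif(49), 7, 7)
  v[3:5, 3:5] <- 0.4 # scale-1 disc around (4,4) is constant
  a <- score_map(grid_meta(7, 7), v)
  b <- rand_score(7, 7, seed = 33)
  cc <- monoscale_cc(a, b, 1)
  expect_false(cc$mask[4, 4])
})

test_that("monoscale maps equal the brute-force window oracle", {
  set.seed(34)
  cases <- expand.grid(rep = 1:4, scale = 1:3)
  for (i in seq_len(nrow(cases))) {
    sc <- cases$scale[i]
    nr <- sample(6:15, 1)
    nc <- sample(6:15, 1)
    mask <- rand_mask(nr, nc, 0.85)
    a <- rand_binary(nr, nc, 0.5, mask = mask)
    b <- rand_binary(nr, nc, 0.5, mask = mask)
    got <- monoscale_kappa(a, b, sc)
    want <- oracle_monoscale(a, b, "kappa", sc)
    vals <- got$values
    vals[!got$mask] <- NA_real_
    expect_equal(vals, want, tolerance = 1e-12)

    x <- rand_score(nr, nc, mask = mask)
    y <- rand_score(nr, nc, mask = mask)
    got_d <- monoscale_distance(x, y, sc)
    want_d <- oracle_monoscale(x, y, "D", sc)
    vd <- got_d$values
    vd[!got_d$mask] <- NA_real_
    expect_equal(vd, want_d, tolerance = 1e-12)

    got_cc <- monoscale_cc(x, y, sc)
    want_cc <- oracle_monoscale(x, y, "CC", sc)
    vc <- got_cc$values
    vc[!got_cc$mask] <- NA_real_
    expect_equal(vc, want_cc, tolerance = 1e-12)
  }
})

test_that("global_index computes the whole-map statistics", {
  set.seed(35)
  mask <- rand_mask(10, 10, 0.9)
  a <- rand_binary(10, 10, 0.5, mask = mask)
  expect_equal(global_index(a, a, "kappa"), 1)
  anti <- binary_map(a$meta, 1 - a$values, a$mask)
  av <- a$values[a$mask]
  if (abs(mean(av) - 0.5) < 0.49) { # both classes present
    expect_lt(global_index(a, anti, "kappa"), 0)
  }

  x <- rand_score(10, 10, mask = mask)
  y <- rand_score(10, 10, mask = mask)
  expect_equal(
    global_index(x, y, "D"),
    mean(abs(x$values[mask] - y$values[mask]))
  )
  expect_equal(global_index(x, y, "CC"), cor(x$values[mask], y$values[mask]))
  flat <- score_map(x$meta, matrix(0.3, 10, 10), mask = mask)
  expect_error(global_index(flat, y, "CC"), "zero variance")
})

test_that("run_cmp aggregates profiles, means and the multiscale map", {
  set.seed(36)
  a <- rand_binary(12, 14, 0.5)
  b <- rand_binary(12, 14, 0.5)
  res <- run_cmp(a, b, "kappa", max_scale = 3)
  expect_equal(res$scales, 1:3)
  expect_equal(nrow(res$profile), 3)
  expect_equal(res$profile_mean, mean(res$profile$value))
  expect_equal(res$global_0, cohen_kappa(confusion(a, b)))

  # profile entries are the means of the monoscale maps
  for (s in 1:3) {
    mono <- res$monoscale[[s]]
    expect_equal(res$profile$value[s], mean(mono$values[mono$mask]))
  }

  # multiscale map = pixel-wise mean over defined scales
  stack <- vapply(res$monoscale, function(m) {
    v <- m$values
    v[!m$mask] <- NA_real_
    v
  }, matrix(0, 12, 14))
  want_ms <- apply(stack, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  })
  got_ms <- res$multiscale$values
  got_ms[!res$multiscale$mask] <- NA_real_
  expect_equal(got_ms, want_ms, tolerance = 1e-12)

  # max_scale = 1: single profile entry equal to the monoscale-1 mean
  res1 <- run_cmp(a, b, "kappa", max_scale = 1)
  m1 <- monoscale_kappa(a, b, 1)
  expect_equal(res1$profile$value, mean(m1$values[m1$mask]))

  # self-comparison: kappa profile of ones, D profile of zeros
  self_k <- run_cmp(a, a, "kappa", max_scale = 3)
  expect_true(all(self_k$profile$value == 1))
  x <- rand_score(12, 14, seed = 37)
  self_d <- run_cmp(x, x, "D", max_scale = 3)
  expect_true(all(self_d$profile$value == 0))
  self_cc <- run_cmp(x, x, "CC", max_scale = 3)
  expect_true(all(abs(self_cc$profile$value - 1) < 1e-12))
})

test_that("run_cmp profile equals independent per-scale brute force", {
  set.seed(38)
  mask <- rand_mask(14, 14, 0.9)
  a <- rand_binary(14, 14, 0.5, mask = mask)
  b <- rand_binary(14, 14, 0.5, mask = mask)
  res <- run_cmp(a, b, "kappa", max_scale = 3)
  for (s in 1:3) {
    want <- oracle_monoscale(a, b, "kappa", s)
    expect_equal(res$profile$value[s], mean(want, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("all three indices are symmetric under argument swap and bounded", {
  set.seed(39)
  for (i in 1:3) {
    mask <- rand_mask(10, 12, 0.9)
    a <- rand_binary(10, 12, 0.5, mask = mask)
    b <- rand_binary(10, 12, 0.5, mask = mask)
    r1 <- run_cmp(a, b, "kappa", max_scale = 3)
    r2 <- run_cmp(b, a, "kappa", max_scale = 3)
    expect_equal(r1$profile$value, r2$profile$value, tolerance = 1e-12)
    expect_true(all(abs(r1$profile$value) <= 1))
    kv <- unlist(lapply(r1$monoscale, function(m) m$values[m$mask]))
    expect_true(all(kv >= -1 - 1e-12 & kv <= 1 + 1e-12))

    x <- rand_score(10, 12, mask = mask)
    y <- rand_score(10, 12, mask = mask)
    for (idx in c("D", "CC")) {
      f1 <- run_cmp(x, y, idx, max_scale = 3)
      f2 <- run_cmp(y, x, idx, max_scale = 3)
      expect_equal(f1$profile$value, f2$profile$value, tolerance = 1e-12)
      expect_equal(f1$global_0, f2$global_0, tolerance = 1e-12)
      vv <- unlist(lapply(f1$monoscale, function(m) m$values[m$mask]))
      if (idx == "D") {
        expect_true(all(vv >= 0 & vv <= 1))
      } else {
        expect_true(all(vv >= -1 - 1e-12 & vv <= 1 + 1e-12))
      }
    }
  }
})

test_that("cmp inputs are type-checked and co-registration enforced", {
  a <- rand_binary(6, 6, 0.5, seed = 40)
  x <- rand_score(6, 6, seed = 41)
  expect_error(run_cmp(x, x, "kappa"))
  mask2 <- matrix(TRUE, 6, 6)
  mask2[3, 3] <- FALSE
  v <- x$values
  v[3, 3] <- NA
  y <- score_map(x$meta, v, mask2)
  expect_error(run_cmp(x, y, "D", max_scale = 2), "co-registered")
})

test_that("tidy, glance and autoplot work on cmp results", {
  a <- rand_binary(8, 8, 0.5, seed = 42)
  b <- rand_binary(8, 8, 0.5, seed = 43)
  res <- run_cmp(a, b, "kappa", max_scale = 2)
  td <- tidy(res)
  expect_named(td, c("index", "scale", "value", "n_defined"))
  gl <- glance(res)
  expect_equal(gl$global_0, res$global_0)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, type = "multiscale"), "ggplot")
})
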