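test_that("weighted mean reduces to forced arithmetic cases", {
  f <- lapply(1:5, function(i) matrix(0.3, 4, 4))
  expect_equal(weighted_mean(f), matrix(0.3, 4, 4))
  # single differing pixel with default weights
  f[[3]][2, 2] <- 1
  expect_equal(weighted_mean(lapply(f, function(m) {m[2,2] <- 0; m}),
                             c(1, 2, 3, 2, 1))[1, 1], 0.3)
  vals <- c(0, 0, 1, 0, 0)
  fr <- lapply(vals, function(v) matrix(v, 2, 2))
  expect_equal(weighted_mean(fr, c(1, 2, 3, 2, 1))[1, 1], 3 / 9)
  # selector weights pick the middle frame exactly
  set.seed(1)
  rf <- lapply(1:5, function(i) matrix(runif(16), 4, 4))
  expect_equal(weighted_mean(rf, c(0, 0, 1, 0, 0)), rf[[3]])
  expect_error(weighted_mean(rf[1:4]), "5 frames")
  expect_error(weighted_mean(rf, c(0, 0, 0, 0, 0)), "weights")
})

test_that("clahe is constant-safe and does not reduce contrast", {
  expect_equal(clahe(matrix(0.5, 32, 32), tile = 8), matrix(0.5, 32, 32))
  chk <- matrix(c(0.45, 0.55), 32, 32)
  out <- clahe(chk, tile = 8)
  expect_gte(diff(range(out)), diff(range(chk)) - 1e-8)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(clahe(matrix(runif(64), 8, 8), tile = 20), "larger")
  expect_error(clahe(matrix(runif(64), 8, 8), tile = 1), ">= 2")
})

test_that("clahe increases vessel/background separation on a faint phantom", {
  set.seed(2)
  f <- band_frame(64, 64, cols = 30:34, bg = 0.62, fg = 0.55)
  f <- pmin(pmax(f + matrix(rnorm(64 * 64, sd = 0.01), 64, 64), 0), 1)
  mask <- matrix(FALSE, 64, 64); mask[, 30:34] <- TRUE
  out <- clahe(f, tile = 16)
  sep_in <- mean(f[!mask]) - mean(f[mask])
  sep_out <- mean(out[!mask]) - mean(out[mask])
  expect_gt(sep_out, sep_in)
})

test_that("median smoothing matches the brute-force oracle", {
  set.seed(3)
  f <- matrix(runif(15 * 15), 15, 15)
  expect_identical(median_smooth(f, 1), f)
  for (k in c(3, 5)) {
    got <- median_smooth(f, k)
    r <- (k - 1) / 2
    ref <- matrix(0, 15, 15)
    for (i in 1:15) for (j in 1:15) {
      ii <- pmin(pmax((i - r):(i + r), 1), 15)
      jj <- pmin(pmax((j - r):(j + r), 1), 15)
      ref[i, j] <- median(f[ii, jj])
    }
    expect_equal(got, ref)
  }
  salt <- matrix(0.4, 9, 9); salt[5, 5] <- 1
  expect_equal(median_smooth(salt, 3), matrix(0.4, 9, 9))
  expect_error(median_smooth(f, 4), "odd")
})

test_that("intensity adjustment is an affine-invariant percentile stretch", {
  set.seed(4)
  x <- matrix(runif(50 * 50), 50, 50)
  expect_equal(adjust_intensity(0.5 * x + 0.2), adjust_intensity(x))
  ramp <- matrix(seq(0.2, 0.6, length.out = 1000), 20, 50)
  out <- adjust_intensity(ramp)
  expect_lt(min(out), 0.02)
  expect_gt(max(out), 0.98)
  expect_warning(adjust_intensity(matrix(0.5, 5, 5)), "constant")
})

test_that("schedules enforce their monotonicities", {
  sch <- level_schedule(seq(0.1, 0.55, by = 0.05))
  expect_equal(nrow(sch), 10)
  expect_true(all(diff(sch$threshold) > 0))
  expect_true(all(diff(sch$clahe_tile) >= 0))
  expect_true(all(diff(sch$median_kernel) <= 0))
  expect_error(level_schedule(c(0.3, 0.2)), "increasing")
  expect_error(level_schedule(c(0.2, 0.3), clahe_tile = c(16, 8)),
               "non-decreasing")
  expect_error(level_schedule(c(0.2, 0.3), median_kernel = c(3, 5)),
               "non-increasing")
  expect_error(level_schedule(c(0.2, 0.3), median_kernel = c(4, 4)), "odd")
})

test_that("data-driven thresholds track the requested pixel fractions", {
  # quantiles track fractions only for continuous histograms, so keep the
  # sensor noise on (a noise-free phantom has intensity atoms)
  set.seed(5)
  ps <- quick_phantom(seed = 5, n_frames = 1)
  f <- render_sequence(ps)$video$frames[[1]]
  sch <- build_schedule(f)
  expect_equal(nrow(sch), 10)
  expect_true(all(diff(sch$threshold) > 0))
  # the level-k threshold admits about the level-k quantile of its own
  # preprocessed image
  e <- sch[1, ]
  pp <- preprocess(f, e)
  expect_equal(mean(pp$image <= e$threshold), 0.10, tolerance = 0.02)
  e <- sch[10, ]
  pp <- preprocess(f, e)
  expect_equal(mean(pp$image <= e$threshold), 0.55, tolerance = 0.05)
  expect_error(build_schedule(matrix(0.5, 32, 32)), "degenerate-histogram")
})

test_that("per-level preprocessing is deterministic and bounded", {
  ps <- quick_phantom(seed = 6, n_frames = 1)
  f <- render_sequence(ps)$video$frames[[1]]
  sch <- build_schedule(f)
  for (k in c(1, 5, 10)) {
    a <- preprocess(f, sch[k, ])
    b <- preprocess(f, sch[k, ])
    expect_identical(a$image, b$image)
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
})
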