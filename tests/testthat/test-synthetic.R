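test_that("phantom generation is deterministic under a fixed seed", {
  ps <- quick_phantom(seed = 11)
  a <- render_sequence(ps)
  b <- render_sequence(ps)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  net <- make_vessel_network(ps)
  expect_identical(net$capillaries, a$truth$vessels)
})

test_that("network counting and containment invariants hold", {
  ps <- quick_phantom(seed = 3, perfused_fraction = 0.6)
  sim <- render_sequence(ps)
  caps <- sim$truth$vessels
  n <- length(caps)
  expect_equal(sum(vapply(caps, function(v) v$perfused, TRUE)),
               ceiling(0.6 * n))
  expect_true(all(sim$truth$vessel_mask[sim$truth$perfused_mask]))
  widths <- vapply(caps, function(v) v$width, 1)
  expect_true(all(widths >= 3 & widths <= 9))
  # empty network
  ps0 <- quick_phantom(seed = 1, n_vessels = 0, n_large = 0)
  expect_length(make_vessel_network(ps0)$capillaries, 0)
  expect_false(any(render_sequence(ps0)$truth$vessel_mask))
})

test_that("distinct capillaries do not overlap", {
  ps <- quick_phantom(seed = 5)
  sim <- render_sequence(ps)
  caps <- sim$truth$vessels
  tubes <- lapply(caps, function(v)
    capdens:::centerline_dist(v$centerline, ps$height, ps$width, 8) <= v$width / 2)
  if (length(tubes) >= 2) {
    acc <- matrix(0L, ps$height, ps$width)
    for (tb in tubes) acc <- acc + tb
    expect_true(all(acc <= 1))
  }
})

test_that("noise-free temporal change is confined to perfused vessels", {
  ps <- quick_phantom(seed = 4, noise_sd = 0, jitter = 0)
  sim <- render_sequence(ps)
  d <- abs(sim$video$frames[[1]] - sim$video$frames[[5]]) > 1e-12
  expect_true(all(sim$truth$perfused_mask[d]))
  # without cells and noise, all frames are identical
  ps0 <- quick_phantom(seed = 4, noise_sd = 0, perfused_fraction = 0)
  sim0 <- render_sequence(ps0)
  expect_identical(sim0$video$frames[[1]], sim0$video$frames[[8]])
})

test_that("injected jitter is recorded and visible in the frames", {
  shifts <- rbind(c(0, 0), c(3, -2), c(3, -2), c(1, 0))
  # static content (no flow) so frames differ by translation only
  ps <- quick_phantom(seed = 6, jitter = shifts, n_frames = 4, noise_sd = 0,
                      perfused_fraction = 0)
  sim <- render_sequence(ps)
  expect_identical(sim$truth$shifts, shifts)
  # frame 2 equals frame 1 translated by (3, -2) away from the pad border
  f1 <- sim$video$frames[[1]]; f2 <- sim$video$frames[[2]]
  expect_equal(f2[10:150, 10:200], f1[7:147, 12:202])
})

test_that("ground-truth FCD matches closed-form geometry", {
  ps <- quick_phantom(seed = 2, n_vessels = 0, n_large = 0)
  sim <- render_sequence(ps)
  roi <- c(1, ps$height, 1, ps$width)
  tf <- true_fcd(sim$truth, roi)
  expect_equal(tf$area_percent, 0)
  expect_equal(tf$length_mm_per_mm2, 0)
  # one synthetic straight perfused bar with known dimensions
  truth <- list(
    perfused_mask = {m <- matrix(FALSE, 100, 100); m[48:52, 11:90] <- TRUE; m},
    vessels = list(list(centerline = cbind(rep(50, 80), 11:90),
                        width = 5, perfused = TRUE)))
  tf2 <- true_fcd(truth, c(1, 100, 1, 100), pixel_size_um = 1.54)
  expect_equal(tf2$area_percent, 100 * (5 * 80) / 1e4)
  expect_equal(tf2$length_mm_per_mm2,
               (79 * 1.54e-3) / (1e4 * (1.54e-3)^2))
  # full-frame perfused block
  truth3 <- list(perfused_mask = matrix(TRUE, 10, 10), vessels = list())
  expect_equal(true_fcd(truth3, c(1, 10, 1, 10))$area_percent, 100)
})

test_that("the hemorrhage preset keeps the network but halves perfusion", {
  b <- render_sequence(phantom_preset("baseline", seed = 9, height = 160,
                                      width = 220))
  h <- render_sequence(phantom_preset("hemorrhage", seed = 9, height = 160,
                                      width = 220))
  expect_identical(b$truth$vessel_mask, h$truth$vessel_mask)
  expect_true(all(b$truth$perfused_mask[h$truth$perfused_mask]))
  expect_lt(sum(h$truth$perfused_mask), sum(b$truth$perfused_mask))
})
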