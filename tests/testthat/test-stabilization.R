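test_that("gaussian gradient is zero on constants and ~slope on ramps", {
  expect_equal(gaussian_gradient(matrix(0.5, 30, 30), 1.5),
               matrix(0, 30, 30))
  s <- 0.004
  ramp <- matrix(rep(s * (1:60), each = 40), 40, 60)
  g <- gaussian_gradient(ramp, 1.5)
  interior <- g[10:30, 10:50]
  expect_lt(max(abs(interior - s)), 1e-8)
  # symmetric ridge at a vertical step edge
  step <- cbind(matrix(0.2, 20, 10), matrix(0.8, 20, 10))
  gs <- gaussian_gradient(step, 1.5)
  expect_equal(which.max(gs[10, ]) %in% c(10, 11), TRUE)
  expect_equal(gs[10, 8], gs[10, 13], tolerance = 1e-10)
  expect_error(gaussian_gradient(ramp, 0), "sigma")
})

test_that("control points hit distinct bright structures, one per tile", {
  f <- matrix(0.5, 99, 99)
  centers <- expand.grid(r = c(17, 50, 83), c = c(17, 50, 83))
  for (k in seq_len(9)) {
    r <- centers$r[k]; c <- centers$c[k]
    f[r, (c - 2):(c + 2)] <- 1
    f[(r - 2):(r + 2), c] <- 1
  }
  cps <- select_control_points(f, sigma = 1.5)
  expect_equal(nrow(cps), 7)
  expect_equal(length(unique(cps$tile_id)), 7)
  # each point within 3 px of a cross centre
  d <- apply(cps, 1, function(p)
    min(abs(centers$r - p["row"]) + abs(centers$c - p["col"])))
  expect_true(all(d <= 6))
  expect_true(all(cps$row > 12 & cps$row <= 87 & cps$col > 12 & cps$col <= 87))
})

test_that("degenerate frames cannot seed control points", {
  expect_error(select_control_points(matrix(0.5, 99, 99)), "degenerate")
  expect_error(select_control_points(matrix(0.5, 50, 50)), "75x75")
})

test_that("structure near the border is moved to interior candidates", {
  f <- matrix(0.5, 99, 99)
  set.seed(3)
  f <- f + matrix(rnorm(99 * 99, sd = 0.01), 99, 99)  # weak texture everywhere
  f[2, 2] <- 1   # dominant response in the border margin
  cps <- select_control_points(f, sigma = 1.5)
  expect_true(all(cps$row > 12 & cps$col > 12))
})

test_that("match_window finds embedded offsets exactly", {
  set.seed(4)
  big <- matrix(runif(80 * 80), 80, 80)
  ref <- big[31:55, 31:55]
  # centred: offset (0,0), score 1
  m0 <- match_window(ref, big[24:63, 24:63])
  expect_equal(m0[c("dy", "dx")], list(dy = 0, dx = 0))
  expect_equal(m0$score, 1)
  # content shifted by (3, -2): out[i,j] = big[i-3, j+2]
  m1 <- match_window(ref, big[(24 - 3):(63 - 3), (24 + 2):(63 + 2)])
  expect_equal(c(m1$dy, m1$dx), c(3, -2))
  # noisy copy at known offset, exhaustively checked
  noisy <- big + matrix(rnorm(6400, sd = 0.05), 80, 80)
  m2 <- match_window(ref, noisy[(24 + 5):(63 + 5), (24 - 4):(63 - 4)])
  expect_equal(c(m2$dy, m2$dx), c(-5, 4))
  expect_error(match_window(matrix(0.2, 25, 25), big[1:40, 1:40]),
               "remarkableness")
})

test_that("injected integer jitter is recovered exactly on a textured scene", {
  f <- textured_frame()
  shifts <- rbind(c(0, 0), c(2, 0), c(-3, 1), c(0, 0), c(4, -5), c(4, -5))
  v <- video_sequence(shifted_stack(f, shifts))
  st <- stabilize(v)
  expect_equal(cbind(st$motion$dy, st$motion$dx), shifts,
               ignore_attr = TRUE)
  # residual motion of aligned frames is zero inside the valid roi
  roi <- st$valid_roi
  a1 <- st$video$frames[[1]][roi[1]:roi[2], roi[3]:roi[4]]
  a5 <- st$video$frames[[5]][roi[1]:roi[2], roi[3]:roi[4]]
  expect_equal(a1, a5)
})

test_that("stabilizing an already-static video is the identity", {
  f <- textured_frame(seed = 9)
  v <- video_sequence(rep(list(f), 6))
  st <- stabilize(v)
  expect_true(all(st$motion$dy == 0 & st$motion$dx == 0))
  expect_equal(st$video$frames, v$frames)
  # idempotence on a stabilized sequence
  st2 <- stabilize(st$video)
  expect_true(all(st2$motion$dy == 0 & st2$motion$dx == 0))
})

test_that("steps beyond the search radius saturate and trigger re-seeding", {
  f <- textured_frame(seed = 5)
  shifts <- rbind(c(0, 0), c(9, 0), c(9, 0))
  v <- video_sequence(shifted_stack(f, shifts))
  st <- stabilize(v)
  expect_true(any(st$motion$saturated))
  expect_true(any(st$motion$reseeded))
  expect_lte(max(abs(st$motion$dy[2])), 7)
})

test_that("shift aggregation tolerates a minority of corrupted points", {
  f <- textured_frame(seed = 6)
  # corrupt 3 of the control-point neighbourhoods with moving blobs
  cps <- select_control_points(f, margin = 20)
  frames <- rep(list(f), 4)
  for (t in 2:4) {
    g <- frames[[t]]
    for (k in 1:3) {
      r <- cps$row[k] + 3 * (t - 1); c <- cps$col[k] + 2 * (t - 1)
      rr <- max(1, r - 2):min(nrow(g), r + 2)
      cc <- max(1, c - 2):min(ncol(g), c + 2)
      g[rr, cc] <- 0
    }
    frames[[t]] <- g
  }
  st <- stabilize(video_sequence(frames))
  expect_true(all(st$motion$dy == 0 & st$motion$dx == 0))
})
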