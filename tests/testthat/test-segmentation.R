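test_that("binarization selects dark pixels and grows with the threshold", {
  expect_false(any(binarize(matrix(0.9, 5, 5), 0.5)))
  f <- band_frame()
  b <- binarize(f, 0.5)
  expect_equal(which(b, arr.ind = TRUE)[, "col"] %in% 4:6, rep(TRUE, 27))
  set.seed(1)
  g <- matrix(runif(400), 20, 20)
  b1 <- binarize(g, 0.3); b2 <- binarize(g, 0.6)
  expect_true(all(b2[b1]))
  expect_error(binarize(g, 1.2), "threshold")
})

test_that("EDT matches the brute-force all-pairs oracle exactly", {
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.6, 20, 20)
    if (all(m)) m[1, 1] <- FALSE
    e <- edt(m)
    expect_equal(e$dist, edt_bruteforce(m))
    # nearest really is a background pixel at the stated distance
    idx <- which(m, arr.ind = TRUE)
    nr <- e$nearest_row[idx]; nc <- e$nearest_col[idx]
    expect_true(all(!m[cbind(nr, nc)]))
    expect_equal(sqrt((idx[, 1] - nr)^2 + (idx[, 2] - nc)^2), e$dist[idx])
  }
})

test_that("EDT handles degenerate masks and breaks ties reproducibly", {
  allbg <- matrix(FALSE, 6, 6)
  e <- edt(allbg)
  expect_true(all(e$dist == 0))
  expect_equal(e$nearest_row, matrix(rep(1:6, 6), 6, 6))
  expect_error(edt(matrix(TRUE, 4, 4)), "no-background")
  # single foreground pixel: four 4-neighbours tie at distance 1;
  # the smaller row wins
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  e <- edt(m)
  expect_equal(e$dist[3, 3], 1)
  expect_equal(c(e$nearest_row[3, 3], e$nearest_col[3, 3]), c(2, 3))
})

test_that("capped EDT is exact below the cutoff", {
  m <- matrix(TRUE, 30, 30); m[1, 1] <- FALSE
  e <- edt(m, max_dist = 5)
  full <- edt_bruteforce(m)
  near <- full <= 5
  expect_equal(e$dist[near], full[near])
  expect_true(all(e$dist[!near] == 5))
  expect_true(all(is.na(e$nearest_row[!near])))
})

test_that("the printed band example yields d = sqrt(20), theta = 135, C = 2", {
  f <- band_frame()
  b <- binarize(f, 0.5)
  e <- edt(b)
  pf <- pixel_features(c(5, 5), b, e, f)
  expect_equal(pf$d, sqrt(20))
  expect_equal(pf$theta, 135)
  expect_equal(pf$C, 2)
  v <- verify_pixels(b, e, f)
  expect_true(v$verified[5, 5])
  # the C++ feature maps agree with the single-pixel reference path
  expect_equal(v$d[5, 5], pf$d)
  expect_equal(v$theta[5, 5], pf$theta)
  expect_equal(v$C[5, 5], pf$C)
})

test_that("isolated pixels are rejected; wide bands fail the diameter test", {
  f <- matrix(0.8, 9, 9); f[5, 5] <- 0.4
  b <- binarize(f, 0.5); e <- edt(b)
  pf <- pixel_features(c(5, 5), b, e, f)
  # background neighbours are their own nearest background, so b_j spread
  # over the 5x5 window; the isolated pixel is dropped by the support rule
  expect_equal(pf$d, sqrt(13))
  expect_false(verify_pixels(b, e, f)$verified[5, 5])
  expect_true(verify_pixels(b, e, f, min_support = 0)$verified[5, 5] ||
              pf$theta <= 130)  # without support it rides on theta alone
  wide <- band_frame(40, 60, cols = 20:40)
  bw <- binarize(wide, 0.5); ew <- edt(bw)
  pw <- pixel_features(c(20, 30), bw, ew, wide)
  expect_gt(pw$d, 13)
  expect_equal(sum(verify_pixels(bw, ew, wide)$verified), 0)
})

test_that("band width sweeps respect the large-vessel exclusion boundary", {
  for (w in c(3, 5, 9)) {
    f <- band_frame(31, 40, cols = 15:(14 + w))
    b <- binarize(f, 0.5)
    v <- verify_pixels(b, edt(b), f)
    expect_gt(sum(v$verified), 0)
  }
  for (w in c(15, 20)) {
    f <- band_frame(40, 60, cols = 20:(19 + w))
    b <- binarize(f, 0.5)
    v <- verify_pixels(b, edt(b), f)
    expect_equal(sum(v$verified), 0)
  }
})

test_that("tightening any verification threshold never adds pixels", {
  ps <- quick_phantom(seed = 7, n_frames = 1)
  f <- render_sequence(ps)$video$frames[[1]]
  sch <- build_schedule(f)
  pp <- preprocess(f, sch[3, ])
  b <- binarize(pp$image, sch$threshold[3])
  e <- edt(b, max_dist = 32)
  base <- verify_pixels(b, e, pp$clahe, verification_params())
  for (p in list(verification_params(P_d = 9),
                 verification_params(P_theta = 150),
                 verification_params(P_C = 1.5))) {
    tight <- verify_pixels(b, e, pp$clahe, p)
    expect_true(all(base$verified[tight$verified]))
  }
  empty <- verify_pixels(b, e, pp$clahe, verification_params(P_d = 0))
  expect_equal(sum(empty$verified), 0)
})

test_that("reconstruction recovers band bodies from verified pixels", {
  f <- band_frame(31, 40, cols = 18:22)   # width-5 band
  b <- binarize(f, 0.5)
  v <- verify_pixels(b, edt(b), f)
  rec <- reconstruct_vessels(v)
  band <- matrix(FALSE, 31, 40); band[, 18:22] <- TRUE
  interior <- band; interior[1:2, ] <- FALSE; interior[30:31, ] <- FALSE
  expect_gt(mean(rec[interior]), 0.95)      # body recovered
  dilated <- matrix(FALSE, 31, 40); dilated[, 16:24] <- TRUE
  expect_true(all(dilated[rec]))            # within 2 px of the band
  # empty verification reconstructs nothing
  v0 <- verify_pixels(b, edt(b), f, verification_params(P_d = 0))
  expect_false(any(reconstruct_vessels(v0)))
})

test_that("isolated interior pixels are filled, open borders are not", {
  m <- matrix(FALSE, 5, 5)
  m[2:4, 2:4] <- TRUE; m[3, 3] <- FALSE
  expect_true(fill_isolated(m)[3, 3])
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2:6] <- TRUE; ring[3:5, 3:5] <- FALSE
  # a 3x3 hole has no isolated interior pixel: left untouched
  expect_identical(fill_isolated(ring), ring)
  # border background is never filled
  col <- matrix(TRUE, 3, 3); col[1, 2] <- FALSE
  expect_identical(fill_isolated(col), col)
})

test_that("segment_frame is definitional: level voting, blank input, determinism", {
  ps <- quick_phantom(seed = 8, n_frames = 1)
  f <- render_sequence(ps)$video$frames[[1]]
  sch <- build_schedule(f)
  expect_error(segment_frame(matrix(0.5, 80, 80), sch), NA)
  # blank frame segments to nothing (thresholds from a real schedule)
  expect_false(any(segment_frame(matrix(0.9, 80, 80), sch)))
  m1 <- segment_frame(f, sch)
  m2 <- segment_frame(f, sch)
  expect_identical(m1, m2)
  # min_level_votes = 1 is the plain union of per-level reconstructions
  u <- matrix(FALSE, nrow(f), ncol(f))
  for (k in seq_len(nrow(sch))) {
    pp <- preprocess(f, sch[k, ])
    b <- binarize(pp$image, sch$threshold[k])
    if (!any(b)) next
    v <- verify_pixels(b, edt(b, max_dist = 32), pp$clahe)
    u <- u | reconstruct_vessels(v)
  }
  got <- segment_frame(f, sch, min_level_votes = 1)
  expect_identical(got, morph_open(fill_isolated(u)))
})

test_that("frame voting implements the more-than-a-quarter rule", {
  set.seed(9)
  masks <- lapply(1:20, function(i) matrix(runif(100) < 0.3, 10, 10))
  votes <- Reduce(`+`, lapply(masks, function(m) m + 0L))
  expect_identical(combine_frames(masks), votes >= 6)       # floor(20/4)+1
  expect_identical(combine_frames(masks[1:4]), Reduce(`+`, lapply(masks[1:4], `+`, 0L)) >= 2)
  expect_identical(combine_frames(masks, min_votes = 1),
                   Reduce(`|`, masks))
  # a pixel on in exactly one mask is off under the default vote
  one <- lapply(1:20, function(i) matrix(FALSE, 4, 4))
  one[[7]][2, 2] <- TRUE
  expect_false(combine_frames(one)[2, 2])
  # on in all masks: on for any vote
  expect_true(combine_frames(lapply(1:6, function(i) matrix(TRUE, 2, 2)),
                             min_votes = 6)[1, 1])
  expect_error(combine_frames(masks[1]), "at least 2")
  expect_error(combine_frames(list(masks[[1]], matrix(TRUE, 3, 3))), "shape")
})
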