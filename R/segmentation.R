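#' Binarize a preprocessed image
#'
#' Vessels absorb the 550 nm illumination and are dark, so a pixel is a
#' vessel candidate iff its intensity is at or below the threshold. Masks
#' grow monotonically with the threshold.
#'
#' @param preprocessed numeric matrix in `[0, 1]`.
#' @param threshold scalar in (0, 1).
#' @return logical matrix, TRUE = vessel candidate.
#' @export
binarize <- function(preprocessed, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("parameter error: threshold must be in (0, 1)", call. = FALSE)
  preprocessed <= threshold
}

#' Euclidean distance transform with nearest-pixel coordinates
#'
#' For every pixel, the exact Euclidean distance to the nearest background
#' pixel and that pixel's coordinates (a background pixel maps to itself at
#' distance 0). Ties between equidistant background pixels are broken by the
#' smaller row, then the smaller column, so lookups are reproducible.
#'
#' @param mask logical matrix, TRUE = foreground; must contain at least one
#'   background pixel (unless `max_dist` is finite).
#' @param max_dist optional distance cutoff: pixels farther than this from
#'   any background pixel get `dist = max_dist` and `NA` coordinates.
#'   Distances below the cutoff are exact. Useful inside the segmentation
#'   pipeline where only small distances matter.
#' @return list of class `edt_result`: `dist` (numeric matrix),
#'   `nearest_row`, `nearest_col` (integer matrices, 1-based).
#' @export
edt <- function(mask, max_dist = Inf) {
  mask <- as_mask(mask)
  if (!is.finite(max_dist) && all(mask))
    stop("no-background error: mask has no background pixel", call. = FALSE)
  res <- .edt_cpp(mask, max_dist)
  class(res) <- "edt_result"
  res
}

#' Pixel-verification thresholds
#'
#' Defaults are the operating point reported for sublingual SDF video:
#' a candidate verifies as capillary when its local diameter `d < P_d`
#' (13 px, about 20 um — excludes venules and larger vessels), its opposite-
#' background angle `theta > P_theta` (130 degrees — enforces curvilinear,
#' band-like geometry) and its contrast ratio `C > P_C` (1.17 — rejects
#' low-contrast background noise).
#'
#' @param P_d maximum diameter, pixels (>= 0).
#' @param P_theta minimum angle, degrees in (0, 180).
#' @param P_C minimum contrast ratio (> 0).
#' @return list of class `verification_params`.
#' @export
verification_params <- function(P_d = 13, P_theta = 130, P_C = 1.17) {
  if (P_d < 0) stop("parameter error: P_d must be >= 0", call. = FALSE)
  if (P_theta <= 0 || P_theta >= 180)
    stop("parameter error: P_theta must be in (0, 180)", call. = FALSE)
  if (P_C <= 0) stop("parameter error: P_C must be > 0", call. = FALSE)
  structure(list(P_d = P_d, P_theta = P_theta, P_C = P_C),
            class = "verification_params")
}

#' Diameter, angle and contrast features of one candidate pixel
#'
#' For candidate `p`, let `b_p` be its nearest background pixel and
#' `b_1..b_24` the nearest background pixels of its 24 neighbours in the
#' 5 x 5 window. The local diameter is `d = max_j ||b_p - b_j||`, attained at
#' the opposite background pixel `b_max`; the angle is taken at `p` in the
#' triangle `(b_p, p, b_max)` by the cosine rule with opposite side `d`
#' (cosine clamped to `[-1, 1]`); the contrast ratio is
#' `C = max_j GL(b_j) / GL(p)` on the CLAHE-enhanced gray image (`+Inf` when
#' `GL(p) = 0`). A large angle certifies that `b_p` and `b_max` lie on
#' opposite sides of a thin band through `p`.
#'
#' @param p integer `(row, col)`, 1-based; must be foreground and at least
#'   2 px from every border.
#' @param mask candidate mask (logical matrix).
#' @param edt an [edt()] result for `mask`.
#' @param gray CLAHE-enhanced intensity image for the level.
#' @return list `(d, theta, C, b_p, b_max)`; `b_p`/`b_max` are `(row, col)`.
#' @export
pixel_features <- function(p, mask, edt, gray) {
  i <- p[1]; j <- p[2]
  h <- nrow(mask); w <- ncol(mask)
  if (i < 3 || j < 3 || i > h - 2 || j > w - 2)
    stop("p lies in the 2-px border margin and is not a candidate",
         call. = FALSE)
  if (!mask[i, j]) stop("p is not a foreground pixel", call. = FALSE)
  bp <- c(edt$nearest_row[i, j], edt$nearest_col[i, j])
  d <- -Inf; bmax <- bp; C <- -Inf
  for (dj in -2:2) for (di in -2:2) {
    if (di == 0 && dj == 0) next
    bj <- c(edt$nearest_row[i + di, j + dj], edt$nearest_col[i + di, j + dj])
    dd <- sqrt(sum((bp - bj)^2))
    if (dd > d) { d <- dd; bmax <- bj }
    glp <- gray[i, j]
    cj <- if (glp <= 0) Inf else gray[bj[1], bj[2]] / glp
    if (cj > C) C <- cj
  }
  a2 <- sum((c(i, j) - bp)^2)
  b2 <- sum((c(i, j) - bmax)^2)
  denom <- 2 * sqrt(a2 * b2)
  theta <- if (denom <= 0) 0 else {
    cv <- max(-1, min(1, (a2 + b2 - d^2) / denom))
    acos(cv) * 180 / pi
  }
  list(d = d, theta = theta, C = C, b_p = bp, b_max = bmax)
}

#' Verify candidate pixels
#'
#' Applies the three feature tests of [pixel_features()] to every foreground
#' pixel outside the 2-px border margin: verified iff `d < P_d` and
#' `theta > P_theta` and `C > P_C`. Verified pixels lie along vessel
#' centerlines; the local diameter is retained for reconstruction.
#'
#' Pixel-wise verification leaves occasional isolated hits on background
#' noise; a vessel centerline, by contrast, verifies as a contiguous chain.
#' Verified pixels with fewer than `min_support` verified 8-neighbours are
#' therefore discarded before reconstruction (set `min_support = 0` for the
#' raw pixel-wise rule).
#'
#' @inheritParams pixel_features
#' @param params a [verification_params()].
#' @param min_support minimum number of verified 8-neighbours a verified
#'   pixel must have (default 2).
#' @return list of class `pixel_verification`: `verified` (logical matrix),
#'   `d_map` (diameters where verified, NA elsewhere), the full feature maps
#'   `d`, `theta`, `C` (NA at non-candidates), and the `b_p` / `b_max`
#'   coordinate maps used for reconstruction.
#' @export
verify_pixels <- function(mask, edt, gray, params = verification_params(),
                          min_support = 2L) {
  mask <- as_mask(mask)
  stopifnot(all(dim(mask) == dim(gray)))
  fm <- .pixel_features_cpp(mask, edt$nearest_row, edt$nearest_col, gray, 2L)
  ver <- mask & !is.na(fm$d) &
    fm$d < params$P_d & fm$theta > params$P_theta & fm$C > params$P_C
  ver[is.na(ver)] <- FALSE
  if (min_support > 0)
    ver <- ver & (neighbor_count8(ver) >= min_support)
  dm <- fm$d
  dm[!ver] <- NA_real_
  structure(list(verified = ver, d_map = dm, d = fm$d, theta = fm$theta,
                 C = fm$C, bp_row = edt$nearest_row, bp_col = edt$nearest_col,
                 bmax_row = fm$bmax_row, bmax_col = fm$bmax_col),
            class = "pixel_verification")
}

#' Reconstruct vessels from verified pixels
#'
#' Each verified pixel knows the two background pixels its diameter spans
#' (`b_p` and the opposite pixel `b_max`); the vessel body is recovered as
#' the union of disks of radius `floor((d - 1) / 2)` centred at the
#' midpoints of these pairs — the local vessel-centre estimates — which
#' reproduces a straight band of width `w` exactly in the continuous limit.
#' Verified pixels themselves are always retained.
#'
#' @param verification a [verify_pixels()] result.
#' @return logical vessel mask.
#' @export
reconstruct_vessels <- function(verification) {
  dm <- verification$d_map
  dm[is.na(dm)] <- 0
  .reconstruct_cpp(as_mask(verification$verified), dm,
                   verification$bp_row, verification$bp_col,
                   verification$bmax_row, verification$bmax_col)
}

#' Fill isolated interior pixels
#'
#' Sets background pixels whose four 4-neighbours are all vessel (isolated
#' interior holes left behind by pixel-wise verification). Out-of-frame
#' neighbours count as background, so border pixels are never filled.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
fill_isolated <- function(mask) {
  mask <- as_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (h < 3 || w < 3) return(mask)
  core <- !mask[2:(h - 1), 2:(w - 1)] &
    mask[1:(h - 2), 2:(w - 1)] & mask[3:h, 2:(w - 1)] &
    mask[2:(h - 1), 1:(w - 2)] & mask[2:(h - 1), 3:w]
  out <- mask
  out[2:(h - 1), 2:(w - 1)] <- mask[2:(h - 1), 2:(w - 1)] | core
  out
}

#' Morphological opening with a radius-1 disk
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
morph_open <- function(mask) {
  kern <- EBImage::makeBrush(3, shape = "diamond")
  m <- matrix(as.numeric(mask), nrow(mask))
  out <- EBImage::dilate(EBImage::erode(m, kern), kern)
  matrix(out > 0.5, nrow(mask))
}

#' Segment one (averaged) frame
#'
#' Runs, for every level of the schedule: preprocessing, binarization, EDT,
#' pixel verification and vessel reconstruction; combines the per-level
#' reconstructions by voting (a pixel is vessel when at least
#' `min_level_votes` levels reconstruct it — levels probe the image with
#' CLAHE tiles of different phase and size, so requiring agreement of two
#' levels suppresses single-level noise and tile-offset width inflation;
#' `min_level_votes = 1` is the plain union); then fills isolated interior
#' pixels and opens with a radius-1 disk.
#'
#' @param mean_frame temporally averaged frame in `[0, 1]`.
#' @param schedule a [level_schedule()].
#' @param params a [verification_params()].
#' @param max_dist EDT cutoff passed to [edt()]; verified capillaries have
#'   centerline distances below `P_d / 2 + 1`, so a cutoff well above `P_d`
#'   changes nothing while bounding work on background-heavy levels.
#' @param min_level_votes number of levels that must agree (default 2).
#' @return logical vessel mask for the frame.
#' @export
segment_frame <- function(mean_frame, schedule,
                          params = verification_params(), max_dist = 32,
                          min_level_votes = 2L) {
  votes <- matrix(0L, nrow(mean_frame), ncol(mean_frame))
  for (k in seq_len(nrow(schedule))) {
    entry <- schedule[k, ]
    pp <- preprocess(mean_frame, entry)
    bin <- binarize(pp$image, entry$threshold)
    if (!any(bin)) next
    ed <- edt(bin, max_dist = max_dist)
    ver <- verify_pixels(bin, ed, pp$clahe, params)
    votes <- votes + (reconstruct_vessels(ver) + 0L)
  }
  morph_open(fill_isolated(votes >= min(min_level_votes, nrow(schedule))))
}

#' Combine per-frame segmentations by voting
#'
#' A pixel is labelled vessel when it is segmented as vessel in at least
#' `min_votes` of the per-frame masks, implementing the "segmented in more
#' than one frame" rule. That rule was stated for temporally *disjoint*
#' five-frame block means — more than one of four masks, i.e. more than a
#' quarter. With sliding five-frame windows, adjacent masks share most of
#' their data and any one-off detection is echoed by its neighbours, so the
#' default vote translates the same fraction to the number of masks at hand:
#' `floor(n / 4) + 1` (2 votes for 4 disjoint masks, 6 for 20 sliding ones).
#' Pass `min_votes` explicitly for the literal count (1 = plain union).
#'
#' @param per_frame_masks list of >= 2 logical matrices of equal size.
#' @param min_votes minimum number of frames voting vessel, or `NULL` for
#'   the fraction-based default.
#' @return logical matrix.
#' @export
combine_frames <- function(per_frame_masks, min_votes = NULL) {
  n <- length(per_frame_masks)
  if (n < 2)
    stop("parameter error: need at least 2 masks", call. = FALSE)
  check_same_shape(per_frame_masks)
  if (is.null(min_votes)) min_votes <- n %/% 4 + 1L
  votes <- Reduce(`+`, lapply(per_frame_masks, function(m) m + 0L))
  votes >= min_votes
}
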