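#' Weighted mean of five consecutive frames
#'
#' Temporal averaging improves connectivity of vessels whose red-cell content
#' comes and goes between frames; the middle frame gets the highest weight so
#' the mean stays anchored in time. Averaging substantially more frames
#' over-smooths moving cells and washes out segmentation-relevant structure.
#'
#' @param frames list of 5 equally sized numeric matrices.
#' @param weights 5 non-negative weights summing to > 0; default `(1,2,3,2,1)`.
#' @return numeric matrix in `[0, 1]`.
#' @export
weighted_mean <- function(frames, weights = c(1, 2, 3, 2, 1)) {
  if (length(frames) != 5 || length(weights) != 5)
    stop("parameter error: need exactly 5 frames and 5 weights", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("parameter error: weights must be non-negative, sum > 0", call. = FALSE)
  check_same_shape(frames)
  out <- 0
  for (i in 1:5) out <- out + weights[i] * frames[[i]]
  out / sum(weights)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise CLAHE on a `[0, 1]` intensity image. The tile edge length in
#' pixels is converted to a tile count per dimension; the image is padded by
#' edge replication to a tile-divisible size, equalized, and cropped back.
#' `clip` follows the normalized clip-limit convention (fraction of the
#' tile histogram mass a bin may hold, times the bin count).
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param tile tile edge length in pixels (>= 2, at most the frame size).
#' @param clip normalized clip limit (> 0); default 0.01.
#' @param bins histogram bins.
#' @return equalized numeric matrix in `[0, 1]`.
#' @export
clahe <- function(frame, tile = 8, clip = 0.01, bins = 256L) {
  if (tile < 2) stop("parameter error: tile must be >= 2", call. = FALSE)
  if (tile > min(dim(frame)))
    stop("parameter error: tile larger than frame", call. = FALSE)
  if (clip <= 0) stop("parameter error: clip must be > 0", call. = FALSE)
  if (diff(range(frame)) == 0) return(frame)
  nx <- max(2L, as.integer(round(nrow(frame) / tile)))
  ny <- max(2L, as.integer(round(ncol(frame) / tile)))
  h <- nrow(frame); w <- ncol(frame)
  hp <- as.integer(ceiling(h / nx) * nx)
  wp <- as.integer(ceiling(w / ny) * ny)
  padded <- frame[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
                  drop = FALSE]
  out <- EBImage::clahe(padded, nx = nx, ny = ny, bins = bins,
                        limit = clip * bins)
  out <- out[seq_len(h), seq_len(w), drop = FALSE]
  pmin(pmax(out, 0), 1)
}

#' Median smoothing
#'
#' Exact `k x k` median filter with edge-replicated borders.
#'
#' @param frame numeric matrix.
#' @param k odd window edge length in pixels (`k = 1` is the identity).
#' @return smoothed matrix.
#' @export
median_smooth <- function(frame, k = 5L) {
  if (k %% 2 != 1 || k < 1)
    stop("parameter error: k must be odd and >= 1", call. = FALSE)
  if (k == 1) return(frame)
  .median_filter_cpp(frame, as.integer(k))
}

#' Percentile contrast stretch
#'
#' Linearly maps the 1st and 99th intensity percentiles to 0 and 1, clipping
#' outside. Affine transforms of the input produce identical output, so the
#' stretch makes threshold levels comparable across recordings.
#'
#' @param frame numeric matrix.
#' @param probs lower/upper percentile pair.
#' @return stretched matrix in `[0, 1]`; a constant frame is returned
#'   unchanged with a warning.
#' @export
adjust_intensity <- function(frame, probs = c(0.01, 0.99)) {
  q <- quantile(frame, probs, names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant frame: adjustment skipped")
    return(frame)
  }
  pmin(pmax((frame - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Threshold-level schedule
#'
#' The segmentation probes the image at 10 increasing threshold levels. Low
#' levels isolate only the darkest (clearest) vessels and use small CLAHE
#' tiles with strong median smoothing; higher levels admit fainter vessels
#' (and background), so the CLAHE tile grows to enhance thin structures and
#' the median kernel shrinks to preserve them. The pixel-verification stage
#' discards the background the high levels let through.
#'
#' @param thresholds strictly increasing vector in (0, 1).
#' @param clahe_tile non-decreasing CLAHE tile sizes, pixels.
#' @param clahe_clip CLAHE clip limit(s).
#' @param median_kernel non-increasing odd median kernel sizes, pixels.
#' @return data.frame of class `level_schedule` with one row per level.
#' @export
level_schedule <- function(thresholds,
                           clahe_tile = c(8, 8, 16, 16, 24, 24, 32, 32, 48, 64),
                           clahe_clip = 0.01,
                           median_kernel = c(7, 7, 7, 5, 5, 5, 5, 3, 3, 3)) {
  n <- length(thresholds)
  if (n < 1) stop("parameter error: empty schedule", call. = FALSE)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  clahe_tile <- rep_len(clahe_tile, n)
  clahe_clip <- rep_len(clahe_clip, n)
  median_kernel <- rep_len(median_kernel, n)
  if (any(diff(clahe_tile) < 0))
    stop("clahe_tile must be non-decreasing", call. = FALSE)
  if (any(diff(median_kernel) > 0))
    stop("median_kernel must be non-increasing", call. = FALSE)
  if (any(median_kernel %% 2 != 1))
    stop("median_kernel entries must be odd", call. = FALSE)
  structure(data.frame(level = seq_len(n), threshold = thresholds,
                       clahe_tile = clahe_tile, clahe_clip = clahe_clip,
                       median_kernel = median_kernel),
            class = c("level_schedule", "data.frame"))
}

#' Build the threshold schedule from reference frames
#'
#' Each level's threshold is an intensity quantile of the pooled histogram
#' of the *level's own preprocessed* training frames — a data-driven
#' stand-in for selecting levels from a training set of recordings. The
#' default quantile grid 0.10, 0.15, ..., 0.55 makes the lowest level admit
#' only the darkest ~10 percent of preprocessed pixels (the wide, clear
#' vessels) while the highest levels admit most vessels plus background,
#' which the pixel verification then prunes. Preprocessing is level-
#' dependent, so the quantile is taken per level on images processed with
#' that level's CLAHE tile and median kernel; at most `max_training` frames
#' (evenly spaced) are pooled.
#'
#' @param reference a numeric matrix or list of matrices (e.g. the averaged
#'   frames of the recording under analysis, or a training set).
#' @param quantile_grid quantile positions, one per level.
#' @param clahe_tile,clahe_clip,median_kernel per-level preprocessing
#'   parameters, as in [level_schedule()].
#' @param max_training maximum number of reference frames pooled per level.
#' @return a [level_schedule()].
#' @export
build_schedule <- function(reference, quantile_grid = seq(0.10, 0.55, by = 0.05),
                           clahe_tile = c(8, 8, 16, 16, 24, 24, 32, 32, 48, 64),
                           clahe_clip = 0.01,
                           median_kernel = c(7, 7, 7, 5, 5, 5, 5, 3, 3, 3),
                           max_training = 3L) {
  if (is.matrix(reference)) reference <- list(reference)
  if (all(vapply(reference, function(m) diff(range(m)) == 0, logical(1))))
    stop("degenerate-histogram error: constant reference input", call. = FALSE)
  if (length(reference) > max_training)
    reference <- reference[unique(round(seq(1, length(reference),
                                            length.out = max_training)))]
  n <- length(quantile_grid)
  clahe_tile <- rep_len(clahe_tile, n)
  clahe_clip <- rep_len(clahe_clip, n)
  median_kernel <- rep_len(median_kernel, n)
  thr <- numeric(n)
  for (k in seq_len(n)) {
    entry <- list(clahe_tile = clahe_tile[k], clahe_clip = clahe_clip[k],
                  median_kernel = median_kernel[k])
    pooled <- unlist(lapply(reference, function(m)
      as.vector(preprocess(m, entry)$image)))
    thr[k] <- quantile(pooled, quantile_grid[k], names = FALSE)
  }
  # level-wise histograms can tie or invert; nudge into strict increase
  eps <- 1e-9
  for (i in seq_along(thr)[-1])
    if (thr[i] <= thr[i - 1]) thr[i] <- thr[i - 1] + eps
  thr <- pmin(pmax(thr, eps), 1 - eps)
  for (i in seq_along(thr)[-1])
    if (thr[i] <= thr[i - 1]) thr[i] <- min(thr[i - 1] + eps, 1 - eps / 2)
  level_schedule(thr, clahe_tile = clahe_tile, clahe_clip = clahe_clip,
                 median_kernel = median_kernel)
}

#' Per-level preprocessing chain
#'
#' CLAHE, then median smoothing, then percentile contrast stretch, with the
#' level's parameters. The CLAHE intermediate is returned alongside the final
#' image because the contrast-ratio feature of the pixel verification is
#' defined on the CLAHE output.
#'
#' @param mean_frame temporally averaged frame, `[0, 1]`.
#' @param entry one row of a [level_schedule()].
#' @return list with `image` (preprocessed, `[0, 1]`) and `clahe`
#'   (the CLAHE intermediate).
#' @export
preprocess <- function(mean_frame, entry) {
  ce <- clahe(mean_frame, tile = entry$clahe_tile, clip = entry$clahe_clip)
  sm <- median_smooth(ce, k = entry$median_kernel)
  adj <- suppressWarnings(adjust_intensity(sm))
  list(image = adj, clahe = ce)
}
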