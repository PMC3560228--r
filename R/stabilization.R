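#' Gaussian-derivative gradient magnitude
#'
#' Filters the frame with the two first-order derivative-of-Gaussian kernels
#' and returns the per-pixel gradient magnitude. The derivative kernel is
#' normalised so that a unit-slope ramp yields magnitude 1.
#'
#' @param frame numeric matrix.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return non-negative numeric matrix of the same size.
#' @export
gaussian_gradient <- function(frame, sigma = 1.5) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("parameter error: sigma must be > 0", call. = FALSE)
  if (length(frame) == 0) stop("empty frame", call. = FALSE)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  dg <- -x * g
  dg <- dg / sum(-x * dg)          # unit response to a unit-slope ramp
  gx <- .sep_filter_cpp(frame, g, dg)   # horizontal derivative
  gy <- .sep_filter_cpp(frame, dg, g)   # vertical derivative
  sqrt(gx^2 + gy^2)
}

# |4-connected 3x3 Laplacian| of an image, edge-replicated.
laplacian_abs <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  left  <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  abs(up + down + left + right - 4 * m)
}

#' Select control points for block matching
#'
#' Control points anchor the stabilization block matching and should sit on
#' distinctive vessel structure (typically branch points). The frame gradient
#' (first-order derivative of Gaussian) is filtered with a 3x3 Laplacian; the
#' frame is partitioned into a 3x3 grid of tiles and the per-tile maxima of
#' the absolute response are ranked, keeping the top `n_points` tiles. Each
#' point is at least `margin` pixels from every border so its matching patch
#' fits inside the frame.
#'
#' @param frame numeric matrix, at least 75 x 75.
#' @param sigma gradient scale in pixels.
#' @param n_points number of control points (7 tiles of the 3x3 grid).
#' @param margin minimum distance to any border in pixels.
#' @return data.frame with columns `row`, `col`, `tile_id`, `response`.
#' @export
select_control_points <- function(frame, sigma = 1.5, n_points = 7L,
                                  margin = 12L) {
  h <- nrow(frame); w <- ncol(frame)
  if (h < 75 || w < 75)
    stop("parameter error: frame smaller than 75x75", call. = FALSE)
  resp <- laplacian_abs(gaussian_gradient(frame, sigma))
  interior <- matrix(FALSE, h, w)
  interior[(margin + 1):(h - margin), (margin + 1):(w - margin)] <- TRUE
  resp[!interior] <- -Inf
  rb <- floor(seq(0, h, length.out = 4))
  cb <- floor(seq(0, w, length.out = 4))
  cand <- data.frame(row = integer(0), col = integer(0), tile_id = integer(0),
                     response = numeric(0))
  tid <- 0L
  for (ti in 1:3) for (tj in 1:3) {
    tid <- tid + 1L
    rs <- (rb[ti] + 1):rb[ti + 1]; cs <- (cb[tj] + 1):cb[tj + 1]
    sub <- resp[rs, cs, drop = FALSE]
    k <- which.max(sub)
    v <- sub[k]
    if (!is.finite(v) || v <= 0) next
    ij <- arrayInd(k, dim(sub))
    cand <- rbind(cand, data.frame(row = rs[1] + ij[1] - 1L,
                                   col = cs[1] + ij[2] - 1L,
                                   tile_id = tid, response = v))
  }
  if (nrow(cand) < n_points)
    stop("degenerate-content error: fewer than ", n_points,
         " tiles with structure", call. = FALSE)
  cand <- cand[order(-cand$response), ][seq_len(n_points), ]
  rownames(cand) <- NULL
  cand
}

#' Match a reference patch inside a search window
#'
#' Exhaustive zero-mean normalized cross-correlation of a 25 x 25 reference
#' patch over all integer offsets in `[-radius, radius]^2` of a 40 x 40
#' search window centred on the reference position. Ties are broken by
#' smaller `|dy| + |dx|`, then smaller `dy`, then smaller `dx`.
#'
#' @param ref 25 x 25 numeric matrix with nonzero variance.
#' @param search 40 x 40 numeric matrix.
#' @param radius search radius (7 = floor((40 - 25) / 2)).
#' @return list `(dy, dx, score)`, score in `[-1, 1]`.
#' @export
match_window <- function(ref, search, radius = 7L) {
  if (!all(dim(ref) == c(25, 25)) || !all(dim(search) == c(40, 40)))
    stop("parameter error: patches must be 25x25 and 40x40", call. = FALSE)
  if (sd(ref) == 0)
    stop("remarkableness error: reference patch has zero variance",
         call. = FALSE)
  rv <- as.vector(ref)
  best <- NULL
  for (dy in -radius:radius) for (dx in -radius:radius) {
    sub <- search[(8 + dy):(32 + dy), (8 + dx):(32 + dx)]
    s <- suppressWarnings(stats::cor(rv, as.vector(sub)))
    if (is.na(s)) s <- -Inf
    if (is.null(best) || s > best$score ||
        (s == best$score &&
         (abs(dy) + abs(dx) < abs(best$dy) + abs(best$dx) ||
          (abs(dy) + abs(dx) == abs(best$dy) + abs(best$dx) &&
           (dy < best$dy || (dy == best$dy && dx < best$dx))))))
      best <- list(dy = dy, dx = dx, score = s)
  }
  best
}

#' Stabilize a video by control-point block matching
#'
#' Control points are selected on the first frame, tracked through adjacent
#' frames by normalized cross-correlation block matching, and the per-step
#' frame shift is the component-wise median of the control-point
#' displacements. Frames are aligned by their integer cumulative shifts with
#' edge-replication padding. When a tracked point drifts too close to a
#' border, or the shift estimate saturates the search radius, the full
#' control-point set is re-seeded on the current frame.
#'
#' @param video a [video_sequence()] with at least 2 frames.
#' @param sigma gradient scale for control-point selection.
#' @param radius block-matching search radius in pixels.
#' @param aggregate how the 7 control-point displacements combine into one
#'   frame shift. `"mode"` (default) takes the most frequent integer
#'   displacement, breaking ties by the smaller shift — control points that
#'   sit on moving blood cells disagree with each other across vessels,
#'   while points anchored on static tissue agree exactly, so plurality
#'   voting stays put even when several points straddle flow. `"median"`
#'   is the component-wise median.
#' @return list with `video` (aligned [video_sequence()]), `motion`
#'   (data.frame `frame`, `dy`, `dx`, `reseeded`, `saturated`; shifts are
#'   cumulative relative to frame 1), and `valid_roi` (the rectangle common
#'   to all aligned frames).
#' @export
stabilize <- function(video, sigma = 1.5, radius = 7L,
                      aggregate = c("mode", "median")) {
  aggregate <- match.arg(aggregate)
  frames <- video$frames
  n <- length(frames)
  if (n < 2) stop("parameter error: need at least 2 frames", call. = FALSE)
  h <- video$height; w <- video$width
  track_margin <- 20L   # a 40x40 search window must fit around each point
  cps <- select_control_points(frames[[1]], sigma, margin = track_margin)
  cum <- matrix(0L, n, 2)
  reseeded <- saturated <- logical(n)
  for (t in 2:n) {
    disp <- matrix(NA_real_, nrow(cps), 2)
    for (k in seq_len(nrow(cps))) {
      r <- cps$row[k]; c <- cps$col[k]
      ref <- frames[[t - 1]][(r - 12):(r + 12), (c - 12):(c + 12)]
      search <- frames[[t]][(r - 19):(r + 20), (c - 19):(c + 20)]
      m <- tryCatch(match_window(ref, search, radius), error = function(e) NULL)
      if (!is.null(m) && is.finite(m$score)) disp[k, ] <- c(m$dy, m$dx)
    }
    ok <- !is.na(disp[, 1])
    if (!any(ok))
      stop(sprintf("stabilization-failure error: no matchable control point at frame %d", t),
           call. = FALSE)
    step <- if (aggregate == "median") {
      c(round(median(disp[ok, 1])), round(median(disp[ok, 2])))
    } else {
      dd <- disp[ok, , drop = FALSE]
      key <- paste(dd[, 1], dd[, 2])
      cnt <- table(key)
      cand <- do.call(rbind, lapply(strsplit(names(cnt)[cnt == max(cnt)], " "),
                                    as.numeric))
      ord <- order(abs(cand[, 1]) + abs(cand[, 2]), cand[, 1], cand[, 2])
      cand[ord[1], ]
    }
    saturated[t] <- any(abs(step) >= radius)
    cum[t, ] <- cum[t - 1, ] + as.integer(step)
    cps$row <- cps$row + as.integer(step[1])
    cps$col <- cps$col + as.integer(step[2])
    off <- cps$row <= track_margin | cps$row > h - track_margin |
           cps$col <= track_margin | cps$col > w - track_margin
    if (saturated[t] || any(off)) {
      cps <- select_control_points(frames[[t]], sigma, margin = track_margin)
      reseeded[t] <- TRUE
    }
  }
  aligned <- vector("list", n)
  for (t in seq_len(n))
    aligned[[t]] <- shift_mat(frames[[t]], -cum[t, 1], -cum[t, 2])
  r0 <- 1 + max(0, -min(cum[, 1])); r1 <- h - max(0, max(cum[, 1]))
  c0 <- 1 + max(0, -min(cum[, 2])); c1 <- w - max(0, max(cum[, 2]))
  list(video = video_sequence(aligned, pixel_size_um = video$pixel_size_um,
                              source_path = video$source_path),
       motion = data.frame(frame = seq_len(n), dy = cum[, 1], dx = cum[, 2],
                           reseeded = reseeded, saturated = saturated),
       valid_roi = roi_rect(r0, r1, c0, c1))
}
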