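# Run expr with a private RNG state seeded at `seed`, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify a synthetic SDF phantom
#'
#' Describes a phantom video emulating sidestream dark field contrast: bright
#' tissue background, dark curvilinear vessels (hemoglobin absorption), red
#' cells advected single-file through perfused vessels with bright plasma
#' gaps between them, stagnant dark content in non-perfused vessels, global
#' translational jitter, and additive Gaussian noise.
#'
#' Perfused vessels are rendered as a plasma-bright tube (`gap_level`, near
#' the tissue background — plasma does not absorb the green illumination)
#' carrying dark cells, so their appearance changes frame to frame exactly
#' where flow exists; non-perfused vessels are a static tube of stagnant
#' cells at `vessel_level`. A uniformly dark, unchanging lumen is
#' indistinguishable from stagnant blood and is correctly "no flow" under
#' temporal differencing.
#'
#' @param height,width frame size in pixels.
#' @param n_vessels number of vessels; default scales with frame height so
#'   the perfused area fraction stays near the sublingual baseline regime
#'   (~12 percent at the default perfused fraction).
#' @param width_range vessel width range in pixels, within `[2, 30]`.
#' @param perfused_fraction fraction of vessels carrying flow.
#' @param background_level,vessel_level,cell_level,gap_level intensities in
#'   `[0, 1]`; requires `cell_level <= vessel_level < background_level`.
#' @param cell_radius red-cell radius in pixels (cells are clipped to the
#'   vessel tube — capillary flow is single file).
#' @param cell_speed mean advection speed, pixels per frame; per-vessel
#'   speeds vary uniformly between 0.9 and 1.2 times it (capillary velocities
#'   are heterogeneous in vivo).
#' @param cell_spacing centre-to-centre cell spacing along the vessel, px;
#'   the default is below the effective cell length, so the column renders
#'   as a quasi-continuous dark tube, as dense single-file flow does.
#' @param gap_len,gap_period plasma-gap train: every `gap_period` px of the
#'   advected cell column, a `gap_len` px window holds no cells. These
#'   bright gaps moving through an otherwise continuous dark column are the
#'   temporal signature of flow that the frame differencing detects.
#' @param n_large number of larger vessels (venules) in the field
#'   (default 0): static
#'   dark structures wider than the capillary diameter cap, present in real
#'   recordings (they anchor stabilization and must be excluded from FCD by
#'   the `P_d` criterion).
#' @param large_width_range,large_level venule width range (px) and
#'   intensity.
#' @param texture_sd amplitude (SD) of an optional static tissue-texture
#'   field (default 0). Static mid-intensity texture at the scale of the
#'   median kernel is indistinguishable from vessel structure for the
#'   pixel-verification geometry, so the default phantom keeps the tissue
#'   optically flat; set a positive value to build stabilization test
#'   scenes with trackable static structure.
#' @param texture_scale correlation length of the texture, pixels; the
#'   default is wide enough that texture valleys fail the capillary
#'   diameter test.
#' @param noise_sd additive (temporal) Gaussian noise SD.
#' @param jitter either a single non-negative integer amplitude (per-step
#'   shifts drawn uniformly from `[-jitter, jitter]`) or an `n_frames x 2`
#'   matrix of cumulative `(dy, dx)` shifts with first row `(0, 0)`.
#' @param n_frames number of frames.
#' @param pixel_size_um micrometres per pixel.
#' @param seed RNG seed; fixed seed gives bit-identical videos.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 480L, width = 640L, n_vessels = NULL,
                         width_range = c(3, 9), perfused_fraction = 0.75,
                         background_level = 0.8, vessel_level = 0.55,
                         cell_level = 0.35, gap_level = 0.80,
                         cell_radius = 4, cell_speed = 4, cell_spacing = 7,
                         gap_len = 30, gap_period = 55,
                         n_large = NULL, large_width_range = c(16, 24),
                         large_level = 0.5,
                         texture_sd = 0, texture_scale = 12,
                         noise_sd = 0.02, jitter = 0L, n_frames = 24L,
                         pixel_size_um = 20 / 13, seed = 1L) {
  if (is.null(n_vessels))
    n_vessels <- max(1L, as.integer(round(26 * (height / 240)^1.5)))
  if (is.null(n_large)) n_large <- 0L
  stopifnot(height >= 32, width >= 32, n_vessels >= 0,
            width_range[1] >= 2, width_range[2] <= 30,
            width_range[1] <= width_range[2],
            perfused_fraction >= 0, perfused_fraction <= 1,
            cell_level <= vessel_level, vessel_level < background_level,
            gap_level <= 1, noise_sd >= 0, n_frames >= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_vessels = as.integer(n_vessels), width_range = width_range,
                 perfused_fraction = perfused_fraction,
                 background_level = background_level,
                 vessel_level = vessel_level, cell_level = cell_level,
                 gap_level = gap_level, cell_radius = cell_radius,
                 cell_speed = cell_speed, cell_spacing = cell_spacing,
                 gap_len = gap_len, gap_period = gap_period,
                 n_large = as.integer(n_large),
                 large_width_range = large_width_range,
                 large_level = large_level,
                 texture_sd = texture_sd, texture_scale = texture_scale,
                 noise_sd = noise_sd, jitter = jitter,
                 n_frames = as.integer(n_frames),
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Phantom presets mirroring the study conditions
#'
#' `"baseline"` is the healthy condition (all-default spec); `"hemorrhage"`
#' keeps the identical vessel network but halves the perfused fraction,
#' mirroring the baseline-versus-hemorrhage contrast used for monotonicity
#' checks.
#'
#' @param preset `"baseline"` or `"hemorrhage"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("baseline", "hemorrhage"), seed = 1L, ...) {
  preset <- match.arg(preset)
  pf <- if (preset == "hemorrhage") 0.75 / 2 else 0.75
  phantom_spec(perfused_fraction = pf, seed = seed, ...)
}

# Piecewise-quadratic curve through control points: Lagrange quadratics
# through consecutive point triples, sampled at sub-pixel spacing.
quad_chain <- function(P, step = 0.4) {
  K <- nrow(P)
  pts <- NULL
  for (i in seq(1, K - 2, by = 2)) {
    A <- P[i, ]; B <- P[i + 1, ]; C <- P[i + 2, ]
    chord <- sqrt(sum((C - A)^2)) + sqrt(sum((B - A)^2))
    nt <- max(8L, ceiling(chord / step))
    t <- seq(0, 1, length.out = nt)
    # quadratic through A (t=0), B (t=0.5), C (t=1)
    L0 <- 2 * (t - 0.5) * (t - 1); L1 <- -4 * t * (t - 1); L2 <- 2 * t * (t - 0.5)
    seg <- cbind(L0 * A[1] + L1 * B[1] + L2 * C[1],
                 L0 * A[2] + L1 * B[2] + L2 * C[2])
    if (!is.null(pts)) seg <- seg[-1, , drop = FALSE]
    pts <- rbind(pts, seg)
  }
  pts
}

# RNG-consuming network builder (no seeding); row/col continuous coordinates.
# Vessels are laid down by rejection sampling so that distinct capillaries do
# not overlap (a 2-px clearance between tubes): in a 2D sublingual field the
# capillaries of interest are distinct curvilinear structures, and perfusion
# is a per-vessel property, so ground-truth labels must not blend vessels.
random_curve <- function(h, w, seg_len) {
  p <- c(runif(1, 5, h - 4), runif(1, 5, w - 4))
  phi <- runif(1, 0, 2 * pi)
  P <- matrix(NA_real_, 5, 2)
  P[1, ] <- p
  for (i in 2:5) {
    phi <- phi + runif(1, -0.6, 0.6)     # curvature-limited turning
    p <- p + seg_len * c(sin(phi), cos(phi))
    P[i, ] <- p
  }
  pts <- quad_chain(P)
  keep <- pts[, 1] >= 1 & pts[, 1] <= h & pts[, 2] >= 1 & pts[, 2] <= w
  # longest in-frame run so each vessel is a single curve
  r <- rle(keep)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  pts[starts[best]:ends[best], , drop = FALSE]
}

make_network_rng <- function(spec) {
  h <- spec$height; w <- spec$width
  occupied <- matrix(FALSE, h, w)   # tubes + clearance
  # larger vessels (venules): static dark structure excluded from FCD by the
  # diameter criterion, but present in the image as it is in real recordings
  large <- vector("list", spec$n_large)
  nl <- 0L
  if (spec$n_large > 0) for (v in seq_len(spec$n_large)) {
    for (attempt in 1:25) {
      pts <- random_curve(h, w, 0.35 * max(h, w))
      if (is.null(pts)) next
      arclen <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                  pts[-nrow(pts), , drop = FALSE])^2)))
      if (arclen < 0.4 * min(h, w)) next
      width <- runif(1, spec$large_width_range[1], spec$large_width_range[2])
      dist_v <- centerline_dist(pts, h, w, max(spec$large_width_range) / 2 + 3)
      tube <- dist_v <= width / 2
      if (any(tube & occupied)) next
      occupied <- occupied | (dist_v <= width / 2 + 3)
      nl <- nl + 1L
      large[[nl]] <- list(centerline = pts, width = width)
      break
    }
  }
  large <- large[seq_len(nl)]

  n <- spec$n_vessels
  vessels <- vector("list", n)
  seg_len <- 0.22 * max(h, w)
  kept <- 0L
  if (n > 0) for (v in seq_len(n)) {
    for (attempt in 1:40) {
      pts <- random_curve(h, w, seg_len)
      if (is.null(pts)) next
      # a vessel must be long enough to carry a cell train with gaps
      arclen <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                  pts[-nrow(pts), , drop = FALSE])^2)))
      if (arclen < max(50, spec$gap_period * 0.75)) next
      width <- runif(1, spec$width_range[1], spec$width_range[2])
      dist_v <- centerline_dist(pts, h, w, max(spec$width_range) / 2 + 3)
      tube <- dist_v <= width / 2
      if (any(tube & occupied)) next       # overlaps an earlier vessel
      occupied <- occupied | (dist_v <= width / 2 + 2)
      kept <- kept + 1L
      vessels[[kept]] <- list(centerline = pts, width = width,
                              perfused = NA,
                              phase = runif(1, 0, spec$cell_spacing),
                              speed_factor = runif(1, 0.9, 1.2))
      break
    }
  }
  vessels <- vessels[seq_len(kept)]
  # perfusion is assigned over the vessels actually laid down
  n_perf <- ceiling(spec$perfused_fraction * kept)
  for (v in seq_len(kept)) vessels[[v]]$perfused <- v <= n_perf
  list(capillaries = vessels, large = large)
}

#' Generate the phantom vessel network
#'
#' @param spec a [phantom_spec()].
#' @return list with `capillaries` (records: `centerline` as an n x 2 matrix
#'   of row/col coordinates, `width` in px, `perfused` flag, `phase` cell
#'   offset) and `large` (venule records: `centerline`, `width`).
#' @export
make_vessel_network <- function(spec) with_seed(spec$seed, make_network_rng(spec))

# distance of every pixel to the rasterized centerline
centerline_dist <- function(pts, h, w, cap) {
  px <- unique(round(pts))
  px <- px[px[, 1] >= 1 & px[, 1] <= h & px[, 2] >= 1 & px[, 2] <= w, ,
           drop = FALSE]
  m <- matrix(TRUE, h, w)
  m[cbind(px[, 1], px[, 2])] <- FALSE
  .edt_cpp(m, cap)$dist
}

#' Render a phantom video with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `video` (a [video_sequence()]) and `truth`: a list with
#'   `vessel_mask`, `perfused_mask` (rendered before jitter), `shifts`
#'   (cumulative per-frame `(dy, dx)`), and `vessels` (the network records).
#' @export
render_sequence <- function(spec) {
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    net <- make_network_rng(spec)
    # jitter: cumulative integer shifts
    if (is.matrix(spec$jitter)) {
      shifts <- spec$jitter
      stopifnot(nrow(shifts) == spec$n_frames, ncol(shifts) == 2)
    } else if (spec$jitter > 0) {
      steps <- matrix(sample(-spec$jitter:spec$jitter,
                             2 * (spec$n_frames - 1), replace = TRUE),
                      ncol = 2)
      shifts <- rbind(c(0, 0), apply(steps, 2, cumsum))
    } else shifts <- matrix(0L, spec$n_frames, 2)

    vessel_mask <- matrix(FALSE, h, w)
    perfused_mask <- matrix(FALSE, h, w)
    large_mask <- matrix(FALSE, h, w)
    base <- matrix(spec$background_level, h, w)
    if (spec$texture_sd > 0) {
      # static tissue texture: smoothed Gaussian field, rescaled to the
      # requested amplitude
      r <- ceiling(3 * spec$texture_scale)
      x <- (-r):r
      g <- exp(-x^2 / (2 * spec$texture_scale^2)); g <- g / sum(g)
      tex <- .sep_filter_cpp(matrix(rnorm(h * w), h, w), g, g)
      tex <- tex / sd(tex) * spec$texture_sd
      base <- base + tex
    }
    for (ves in net$large) {
      blur <- 5   # venules lie deeper in the tissue and image with soft edges
      dist_v <- centerline_dist(ves$centerline, h, w,
                                max(spec$large_width_range) / 2 + blur + 3)
      tube <- dist_v <= ves$width / 2
      large_mask <- large_mask | tube
      f <- pmin(pmax((dist_v - ves$width / 2) / blur, 0), 1)
      prof <- spec$large_level * (1 - f) + spec$background_level * f
      base <- pmin(base, prof)
    }
    caps <- net$capillaries
    cap <- max(spec$width_range) / 2 + spec$cell_radius + 3
    tubes <- vector("list", length(caps))
    for (v in seq_along(caps)) {
      ves <- caps[[v]]
      dist_v <- centerline_dist(ves$centerline, h, w, cap)
      tube <- dist_v <= ves$width / 2
      tubes[[v]] <- tube
      vessel_mask <- vessel_mask | tube
      if (ves$perfused) {
        perfused_mask <- perfused_mask | tube
        base[tube] <- pmin(base[tube], spec$gap_level)
      } else {
        base[tube] <- pmin(base[tube], spec$vessel_level)
      }
    }

    frames <- vector("list", spec$n_frames)
    # inside a capillary, red cells deform to fill the lumen: the rendered
    # disk spans the tube width (clipped to the tube), so the sides of a
    # dense column coincide with the static tube boundary and only gap
    # fronts move
    doffs <- lapply(caps, function(ves) {
      r <- max(spec$cell_radius, ves$width / 2 + 1)
      dd <- expand.grid(di = -ceiling(r):ceiling(r), dj = -ceiling(r):ceiling(r))
      dd[dd$di^2 + dd$dj^2 <= r^2, ]
    })
    for (t in seq_len(spec$n_frames)) {
      fr <- base
      for (v in seq_along(caps)) {
        ves <- caps[[v]]
        if (!ves$perfused) next
        pts <- ves$centerline
        seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                                pts[-nrow(pts), , drop = FALSE])^2))
        cum <- c(0, cumsum(seglen))
        L <- cum[length(cum)]
        if (L < spec$cell_spacing) next
        # cell train in its own (advected) coordinate: densely spaced cells
        # with periodic plasma-gap windows carved out
        u <- (0:(floor(L / spec$cell_spacing) - 1)) * spec$cell_spacing
        if (spec$gap_len > 0 && spec$gap_period > spec$gap_len)
          u <- u[(u %% spec$gap_period) >= spec$gap_len]
        if (length(u) == 0) next
        s <- (ves$phase + u + (t - 1) * spec$cell_speed * ves$speed_factor) %% L
        cy <- approx(cum, pts[, 1], xout = s)$y
        cx <- approx(cum, pts[, 2], xout = s)$y
        tube <- tubes[[v]]
        doff <- doffs[[v]]
        for (k in seq_along(s)) {
          ii <- round(cy[k]) + doff$di
          jj <- round(cx[k]) + doff$dj
          ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
          idx <- cbind(ii[ok], jj[ok])
          idx <- idx[tube[idx], , drop = FALSE]   # single-file: clip to tube
          if (nrow(idx)) fr[idx] <- pmin(fr[idx], spec$cell_level)
        }
      }
      if (spec$noise_sd > 0)
        fr <- fr + matrix(rnorm(h * w, sd = spec$noise_sd), h, w)
      fr <- pmin(pmax(fr, 0), 1)
      frames[[t]] <- shift_mat(fr, shifts[t, 1], shifts[t, 2])
    }
    list(video = video_sequence(frames, pixel_size_um = spec$pixel_size_um,
                                source_path = sprintf("phantom(seed=%d)", spec$seed)),
         truth = list(vessel_mask = vessel_mask, perfused_mask = perfused_mask,
                      large_mask = large_mask, shifts = shifts,
                      vessels = caps, large = net$large))
  })
}

#' Ground-truth FCD of a phantom
#'
#' Area-based FCD from the perfused mask and length-based FCD from the
#' analytic centerline length of perfused vessels, both restricted to the
#' region of interest — the same formulas the pipeline applies to its
#' detected active mask.
#'
#' @param truth the `truth` element of [render_sequence()].
#' @param roi rectangle `c(row0, row1, col0, col1)`.
#' @param pixel_size_um micrometres per pixel.
#' @return list `(area_percent, length_mm_per_mm2)`.
#' @export
true_fcd <- function(truth, roi, pixel_size_um = 20 / 13) {
  area <- 100 * sum(roi_crop(truth$perfused_mask, roi)) / roi_area(roi)
  len_px <- 0
  for (ves in truth$vessels) {
    if (!ves$perfused) next
    pts <- ves$centerline
    inroi <- pts[, 1] >= roi[1] & pts[, 1] <= roi[2] &
             pts[, 2] >= roi[3] & pts[, 2] <= roi[4]
    both <- inroi[-1] & inroi[-length(inroi)]
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
    len_px <- len_px + sum(seg[both])
  }
  len_mm <- len_px * pixel_size_um * 1e-3
  area_mm2 <- roi_area(roi) * (pixel_size_um * 1e-3)^2
  list(area_percent = area, length_mm_per_mm2 = len_mm / area_mm2)
}
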