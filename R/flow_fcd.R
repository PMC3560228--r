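#' Per-pixel segmentation-change counts
#'
#' Counts, for every pixel, how many times its segmentation label flips
#' between consecutive per-frame masks. Pixels inside perfused vessels flip
#' as red cells and plasma gaps pass; stagnant vessels and background do not.
#'
#' @param per_frame_masks list of >= 2 logical matrices (nominally 20).
#' @return list of class `activity_map`: `transitions` (integer matrix),
#'   `n_pairs` (number of consecutive pairs).
#' @export
activity_map <- function(per_frame_masks) {
  n <- length(per_frame_masks)
  if (n < 2) stop("parameter error: need at least 2 masks", call. = FALSE)
  check_same_shape(per_frame_masks)
  acc <- matrix(0L, nrow(per_frame_masks[[1]]), ncol(per_frame_masks[[1]]))
  for (t in seq_len(n - 1))
    acc <- acc + abs((per_frame_masks[[t]] + 0L) - (per_frame_masks[[t + 1]] + 0L))
  structure(list(transitions = acc, n_pairs = n - 1L), class = "activity_map")
}

#' Classify perfused (active) vessels
#'
#' A pixel is flow-positive when it is vessel in the combined mask and its
#' segmentation flipped at least `t_flow` times. With `component_vote` on
#' (default), each 8-connected component of the combined mask is kept or
#' dropped wholly according to whether at least `vote_frac` of its pixels are
#' flow-positive — pixel-level flow flags are salt-and-pepper on real video,
#' while perfusion is a property of the whole vessel. Turn the vote off for
#' the literal per-pixel rule.
#'
#' @param combined combined vessel mask (logical matrix).
#' @param act an [activity_map()].
#' @param t_flow minimum number of transitions (>= 1). The default of 2
#'   requires a pixel to disappear and reappear — one full plasma-gap
#'   passage; frame voting upstream already removes one-shot noise.
#' @param component_vote keep/drop whole components by majority.
#' @param vote_frac fraction of flow-positive pixels required to keep a
#'   component.
#' @return logical mask of active vessels (always a subset of `combined`).
#' @export
classify_active <- function(combined, act, t_flow = 2L, component_vote = TRUE,
                            vote_frac = 0.5) {
  combined <- as_mask(combined)
  stopifnot(all(dim(combined) == dim(act$transitions)))
  if (t_flow < 1) stop("parameter error: t_flow must be >= 1", call. = FALSE)
  flow <- combined & (act$transitions >= t_flow)
  if (!component_vote) return(flow)
  lab <- .label_cpp(combined)
  nlab <- max(lab)
  if (nlab == 0) return(flow & FALSE)
  tot <- tabulate(lab[combined], nbins = nlab)
  hot <- tabulate(lab[flow], nbins = nlab)
  keep <- which(hot / tot >= vote_frac)
  combined & matrix(lab %in% keep, nrow(lab))
}

#' Area-based functional capillary density
#'
#' Percentage of the region of interest covered by active vessels.
#'
#' @param active active-vessel mask (logical matrix).
#' @param roi rectangle `c(row0, row1, col0, col1)`, 1-based inclusive.
#' @return percentage in `[0, 100]`.
#' @export
fcd_area <- function(active, roi) {
  if (roi[2] > nrow(active) || roi[4] > ncol(active))
    stop("parameter error: roi exceeds frame", call. = FALSE)
  sub <- roi_crop(active, roi)
  100 * sum(sub) / length(sub)
}

# Skeleton length by step counting: 1 per 4-neighbour step, sqrt(2) per
# diagonal step, each adjacent pixel pair counted once.
skeleton_length_px <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  if (h < 2 || w < 2) return(0)
  horiz <- sum(skel[, -w] & skel[, -1])
  vert <- sum(skel[-h, ] & skel[-1, ])
  diag1 <- sum(skel[-h, -w] & skel[-1, -1])
  diag2 <- sum(skel[-h, -1] & skel[-1, -w])
  horiz + vert + sqrt(2) * (diag1 + diag2)
}

#' Length-based functional capillary density
#'
#' Skeletonizes the active vessels inside the region of interest
#' (topology-preserving thinning) and reports skeleton length per unit
#' tissue area, in mm per mm^2.
#'
#' @inheritParams fcd_area
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return length density in mm/mm^2.
#' @export
fcd_length <- function(active, roi, pixel_size_um = 20 / 13) {
  if (pixel_size_um <= 0)
    stop("parameter error: pixel_size_um must be > 0", call. = FALSE)
  sub <- roi_crop(as_mask(active), roi)
  skel <- .skeletonize_cpp(sub)
  len_mm <- skeleton_length_px(skel) * pixel_size_um * 1e-3
  area_mm2 <- nrow(sub) * ncol(sub) * (pixel_size_um * 1e-3)^2
  len_mm / area_mm2
}

#' Bundle FCD measurements
#'
#' @param fcd_area_percent area-based FCD, percent of ROI.
#' @param fcd_length_mm_per_mm2 length-based FCD.
#' @param roi the ROI rectangle used.
#' @param pixel_size_um micrometres per pixel.
#' @param active_mask the active-vessel mask.
#' @param frames_used number of frames analysed.
#' @return list of class `fcd_result` (also carries `roi_area_px`).
#' @export
fcd_result <- function(fcd_area_percent, fcd_length_mm_per_mm2, roi,
                       pixel_size_um, active_mask = NULL, frames_used = NA) {
  stopifnot(fcd_area_percent >= 0, fcd_area_percent <= 100,
            fcd_length_mm_per_mm2 >= 0)
  structure(list(fcd_area_percent = fcd_area_percent,
                 fcd_length_mm_per_mm2 = fcd_length_mm_per_mm2,
                 roi = roi, roi_area_px = roi_area(roi),
                 pixel_size_um = pixel_size_um, active_mask = active_mask,
                 frames_used = frames_used),
            class = "fcd_result")
}

#' @export
print.fcd_result <- function(x, ...) {
  cat(sprintf("<fcd_result> area-based %.2f %%, length-based %.4g mm/mm^2 (roi %d px, %d frames)\n",
              x$fcd_area_percent, x$fcd_length_mm_per_mm2, x$roi_area_px,
              as.integer(x$frames_used)))
  invisible(x)
}
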