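#' Video sequence container
#'
#' An ordered stack of equally sized intensity frames together with the
#' physical pixel pitch. Frames are numeric matrices with values in `[0, 1]`,
#' indexed `(row, col)` with row 1 at the top. Under SDF/OPS contrast vessels
#' (hemoglobin) are dark on a bright tissue background.
#'
#' @param frames list of numeric matrices in `[0, 1]`, all the same size.
#' @param pixel_size_um micrometres per pixel (> 0). The default corresponds
#'   to a 13-px capillary diameter cap equating to roughly 20 um.
#' @param source_path optional provenance string.
#' @return An object of class `video_sequence` with elements `frames`,
#'   `height`, `width`, `pixel_size_um`, `source_path`.
#' @export
video_sequence <- function(frames, pixel_size_um = 20 / 13, source_path = "") {
  if (!is.list(frames) || length(frames) == 0L)
    stop("empty-input error: no frames", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape error: frames differ in size", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("intensity out of [0,1]", call. = FALSE)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0", call. = FALSE)
  structure(list(frames = frames, height = dims[1, 1], width = dims[2, 1],
                 pixel_size_um = pixel_size_um, source_path = source_path),
            class = "video_sequence")
}

#' @export
print.video_sequence <- function(x, ...) {
  cat(sprintf("<video_sequence> %d frames, %d x %d px, %.3f um/px\n",
              length(x$frames), x$height, x$width, x$pixel_size_um))
  invisible(x)
}

#' @export
length.video_sequence <- function(x) length(x$frames)

# Reduce a decoded frame array to a 2D intensity matrix. SDF illumination is
# 550 nm green, so the green channel carries the hemoglobin contrast; luma is
# available as an override.
frame_to_gray <- function(a, channel = c("green", "luma")) {
  channel <- match.arg(channel)
  if (length(dim(a)) == 2L) return(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 1L) return(a[, , 1])
    if (channel == "green") return(a[, , 2])
    return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
  }
  stop("input-format error: cannot interpret frame array", call. = FALSE)
}

#' Load a microcirculation video
#'
#' Reads a multi-page TIFF stack, a single TIFF/PNG image, or a directory of
#' numbered per-frame TIFF/PNG images (sorted by file name). RGB input is
#' reduced to the green channel by default (SDF contrast lives at 550 nm).
#' Intensities are normalised by the container's representable maximum, not
#' the observed maximum, so thresholds are comparable across frames; `tiff`
#' and `png` readers already return values on that `[0, 1]` scale.
#' AVI/MP4 containers are not decoded; convert such recordings to a TIFF
#' stack (e.g. `ffmpeg -i in.avi out.tif`) first.
#'
#' @param path file or directory path.
#' @param max_frames maximum number of frames to keep, in temporal order.
#' @param pixel_size_um micrometres per pixel for the recording.
#' @param channel `"green"` (default) or `"luma"` reduction for RGB input.
#' @return A [video_sequence()].
#' @export
load_video <- function(path, max_frames = Inf, pixel_size_um = 20 / 13,
                       channel = c("green", "luma")) {
  channel <- match.arg(channel)
  if (!file.exists(path))
    stop("input-format error: path does not exist: ", path, call. = FALSE)
  if (!is.numeric(max_frames) || max_frames < 1)
    stop("max_frames must be a positive number", call. = FALSE)
  read_one <- function(f) {
    ext <- tolower(tools::file_ext(f))
    a <- switch(ext,
      tif = , tiff = tiff::readTIFF(f, all = TRUE),
      png = list(png::readPNG(f)),
      stop("input-format error: unsupported container '.", ext,
           "'; supported: multi-page TIFF, PNG, or a directory of frames",
           call. = FALSE))
    a
  }
  if (dir.exists(path)) {
    fs <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                          ignore.case = TRUE, full.names = TRUE))
    if (length(fs) == 0L)
      stop("empty-input error: no frame images in directory", call. = FALSE)
    pages <- list()
    for (f in fs) {
      pages <- c(pages, read_one(f))
      if (length(pages) >= max_frames) break
    }
  } else {
    pages <- read_one(path)
  }
  if (length(pages) == 0L) stop("empty-input error: zero frames", call. = FALSE)
  pages <- pages[seq_len(min(length(pages), max_frames))]
  frames <- lapply(pages, frame_to_gray, channel = channel)
  frames <- lapply(frames, function(m) pmin(pmax(m, 0), 1))
  video_sequence(frames, pixel_size_um = pixel_size_um, source_path = path)
}

#' Write segmentation masks and FCD results
#'
#' Masks are written as single-channel PNG images (0 = background,
#' 1 = vessel); results as both CSV and JSON with fields
#' `fcd_area_percent`, `fcd_length_mm_per_mm2`, `roi_area_px`, `frames_used`.
#'
#' @param masks list of logical matrices (may be empty).
#' @param results an `fcd_result` (see [fcd_area()] / [analyze_video()]), or
#'   a plain list carrying the fields above.
#' @param out_dir writable output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(masks, results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("I/O error: cannot create output directory", call. = FALSE)
  written <- character(0)
  for (i in seq_along(masks)) {
    f <- file.path(out_dir, sprintf("mask_%03d.png", i))
    png::writePNG(matrix(as.numeric(masks[[i]]), nrow(masks[[i]])), f)
    written <- c(written, f)
  }
  rec <- list(
    fcd_area_percent = as.numeric(results$fcd_area_percent),
    fcd_length_mm_per_mm2 = as.numeric(results$fcd_length_mm_per_mm2),
    roi_area_px = as.numeric(results$roi_area_px),
    frames_used = as.numeric(results$frames_used))
  csv <- file.path(out_dir, "fcd_results.csv")
  write.csv(as.data.frame(rec), csv, row.names = FALSE)
  js <- file.path(out_dir, "fcd_results.json")
  jsonlite::write_json(rec, js, auto_unbox = TRUE, digits = NA)
  invisible(c(written, csv, js))
}

#' Read a mask image back as a logical matrix
#' @param path PNG mask written by [write_outputs()].
#' @return logical matrix, TRUE = vessel.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
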