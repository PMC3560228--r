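#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default operating point:
#' 20 analysed frames, block-matching stabilization (sigma 1.5 px, search
#' radius 7), the 10-level threshold schedule, verification thresholds
#' `P_d = 13` px / `P_theta = 130` deg / `P_C = 1.17`, more-than-a-quarter
#' frame voting (6 of 20), region growing capped at 10 steps, flow threshold
#' of 2 transitions with whole-component voting, and a pixel pitch of
#' 20/13 um (13 px spanning a ~20 um capillary).
#'
#' @param frames_to_use number of frame positions analysed.
#' @param stabilize run stabilization (disable for tripod-stable input).
#' @param sigma control-point gradient scale, px.
#' @param weights 5-frame temporal averaging weights.
#' @param quantile_grid threshold quantile positions for [build_schedule()].
#' @param schedule optional explicit [level_schedule()] overriding the
#'   data-driven one.
#' @param params a [verification_params()].
#' @param min_votes frame votes required in [combine_frames()] (`NULL` =
#'   fraction-based default, more than a quarter of the masks).
#' @param min_level_votes level votes required in [segment_frame()].
#' @param region_grow run orientation-guided region growing.
#' @param max_grow_steps growth cap per endpoint.
#' @param t_flow transition threshold of [classify_active()].
#' @param component_vote,vote_frac component-level flow voting.
#' @param pixel_size_um micrometres per pixel.
#' @param edt_max_dist EDT cutoff inside [segment_frame()].
#' @param verbose log per-stage progress to stderr.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_to_use = 20L, stabilize = TRUE,
                            sigma = 1.5, weights = c(1, 2, 3, 2, 1),
                            quantile_grid = seq(0.10, 0.55, by = 0.05),
                            schedule = NULL,
                            params = verification_params(),
                            min_votes = NULL, region_grow = TRUE,
                            min_level_votes = 2L,
                            max_grow_steps = 10L, t_flow = 2L,
                            component_vote = TRUE, vote_frac = 0.5,
                            pixel_size_um = 20 / 13, edt_max_dist = 32,
                            verbose = FALSE) {
  structure(list(frames_to_use = as.integer(frames_to_use),
                 stabilize = stabilize, sigma = sigma, weights = weights,
                 quantile_grid = quantile_grid, schedule = schedule,
                 params = params,
                 min_votes = if (is.null(min_votes)) NULL else as.integer(min_votes),
                 region_grow = region_grow,
                 min_level_votes = as.integer(min_level_votes),
                 max_grow_steps = as.integer(max_grow_steps),
                 t_flow = as.integer(t_flow),
                 component_vote = component_vote, vote_frac = vote_frac,
                 pixel_size_um = pixel_size_um, edt_max_dist = edt_max_dist,
                 verbose = verbose),
            class = "pipeline_config")
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose))
    message(sprintf("[capdens] %s", sprintf(fmt, ...)))
}

#' Analyze a microcirculation video end to end
#'
#' Runs the full chain: load (if given a path), stabilize, 5-frame weighted
#' temporal averaging at each of `frames_to_use` frame positions (sliding,
#' clamped at the ends), data-driven threshold schedule, per-frame
#' multi-level segmentation, 2-of-n frame voting, bridge/fill/spur
#' morphology, orientation-guided region growing, temporal-difference flow
#' classification, and area- and length-based FCD over the stabilized ROI
#' (shrunk by the 2-px verification margin).
#'
#' @param video a [video_sequence()] or a path readable by [load_video()].
#' @param config a [pipeline_config()].
#' @return list of class `capdens_analysis`: `result` (an [fcd_result()]),
#'   `combined` and `active` masks, `per_frame_masks`, `activity`
#'   ([activity_map()]), `motion`, `valid_roi`, `roi`, `schedule`, `config`.
#' @export
analyze_video <- function(video, config = pipeline_config()) {
  if (is.character(video))
    video <- load_video(video, pixel_size_um = config$pixel_size_um)
  n_frames <- length(video$frames)
  h <- video$height; w <- video$width

  motion <- NULL
  valid_roi <- roi_rect(1, h, 1, w)
  if (config$stabilize && n_frames >= 2) {
    st <- tryCatch(stabilize(video, sigma = config$sigma),
                   error = function(e) e)
    if (inherits(st, "error")) {
      warning("stabilization failed (", conditionMessage(st),
              "); continuing unstabilized")
    } else {
      video <- st$video
      motion <- st$motion
      valid_roi <- st$valid_roi
      log_stage(config, "stabilized %d frames, roi %dx%d", n_frames,
                valid_roi[2] - valid_roi[1] + 1, valid_roi[4] - valid_roi[3] + 1)
    }
  }

  n_use <- min(config$frames_to_use, n_frames)
  mean_frames <- vector("list", n_use)
  for (i in seq_len(n_use)) {
    c0 <- min(max(i, 3), n_frames - 2)          # clamp 5-frame window
    if (n_frames < 5) {
      idx <- rep(seq_len(n_frames), length.out = 5)
    } else idx <- (c0 - 2):(c0 + 2)
    mean_frames[[i]] <- weighted_mean(video$frames[idx], config$weights)
  }
  log_stage(config, "averaged %d frame positions", n_use)

  blank <- all(vapply(mean_frames, function(m) diff(range(m)) == 0, logical(1)))
  schedule <- config$schedule
  if (is.null(schedule) && !blank)
    schedule <- build_schedule(mean_frames, quantile_grid = config$quantile_grid)

  roi <- roi_rect(min(valid_roi[1] + 2, h - 2), max(valid_roi[2] - 2, 3),
                  min(valid_roi[3] + 2, w - 2), max(valid_roi[4] - 2, 3))

  if (blank) {
    empty <- matrix(FALSE, h, w)
    res <- fcd_result(0, 0, roi, config$pixel_size_um, empty, n_use)
    return(structure(list(result = res, combined = empty, active = empty,
                          per_frame_masks = rep(list(empty), n_use),
                          activity = NULL, motion = motion,
                          valid_roi = valid_roi, roi = roi,
                          schedule = schedule, config = config),
                     class = "capdens_analysis"))
  }

  per_frame <- vector("list", n_use)
  for (i in seq_len(n_use)) {
    per_frame[[i]] <- segment_frame(mean_frames[[i]], schedule, config$params,
                                    max_dist = config$edt_max_dist,
                                    min_level_votes = config$min_level_votes)
    log_stage(config, "segmented frame %d/%d (%d px)", i, n_use,
              sum(per_frame[[i]]))
  }

  combined <- if (n_use >= 2) combine_frames(per_frame, config$min_votes)
              else per_frame[[1]]
  combined <- morph_postprocess(combined)
  if (config$region_grow) {
    overall_gray <- suppressWarnings(
      adjust_intensity(Reduce(`+`, mean_frames) / n_use))
    combined <- region_grow(combined, overall_gray,
                            max_steps = config$max_grow_steps)
  }
  log_stage(config, "combined mask: %d px", sum(combined))

  if (n_use >= 2) {
    act <- activity_map(per_frame)
    active <- classify_active(combined, act, t_flow = config$t_flow,
                              component_vote = config$component_vote,
                              vote_frac = config$vote_frac)
  } else {
    act <- NULL
    active <- combined & FALSE
  }
  log_stage(config, "active mask: %d px", sum(active))

  res <- fcd_result(fcd_area(active, roi),
                    fcd_length(active, roi, config$pixel_size_um),
                    roi, config$pixel_size_um, active, n_use)
  structure(list(result = res, combined = combined, active = active,
                 per_frame_masks = per_frame, activity = act, motion = motion,
                 valid_roi = valid_roi, roi = roi, schedule = schedule,
                 config = config),
            class = "capdens_analysis")
}

#' @export
print.capdens_analysis <- function(x, ...) {
  print(x$result)
  invisible(x)
}
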