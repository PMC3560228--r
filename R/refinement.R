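# Lookup table for the bridge operator: for each 3x3 neighbourhood
# configuration of the 8 ring positions, TRUE when the foreground neighbours
# fall into >= 2 components that are not 8-connected to each other inside the
# neighbourhood (the centre being background). Built once, cached.
bridge_lut <- local({
  lut <- NULL
  function() {
    if (!is.null(lut)) return(lut)
    offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                  c(0, 1), c(1, -1), c(1, 0), c(1, 1))
    adj <- outer(seq_len(8), seq_len(8), Vectorize(function(a, b)
      a != b && max(abs(offs[a, ] - offs[b, ])) <= 1))
    out <- logical(256)
    for (cfg in 0:255) {
      on <- which(bitwAnd(cfg, bitwShiftL(1L, 0:7)) != 0)
      if (length(on) < 2) next
      seen <- logical(8)
      ncomp <- 0L
      for (s in on) {
        if (seen[s]) next
        ncomp <- ncomp + 1L
        stack <- s
        while (length(stack)) {
          v <- stack[[1]]; stack <- stack[-1]
          if (seen[v]) next
          seen[v] <- TRUE
          nb <- on[adj[v, on] & !seen[on]]
          stack <- c(stack, nb)
        }
      }
      out[cfg + 1] <- ncomp >= 2
    }
    lut <<- out
    lut
  }
})

# Neighbourhood configuration index (0..255) of every pixel; out-of-frame
# neighbours count as background.
neighbor_config <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  cfg <- matrix(0L, h, w)
  m <- matrix(as.integer(mask), h, w)
  for (k in seq_len(8)) {
    dy <- offs[k, 1]; dx <- offs[k, 2]
    sh <- matrix(0L, h, w)
    rs <- max(1, 1 + dy):min(h, h + dy)
    cs <- max(1, 1 + dx):min(w, w + dx)
    sh[rs, cs] <- m[rs - dy, cs - dx]
    cfg <- cfg + sh * bitwShiftL(1L, k - 1L)
  }
  cfg
}

#' Bridge, fill and spur morphology
#'
#' Post-processing of the combined vessel mask, in order: *bridge* (turn on a
#' background pixel whose 3x3 neighbourhood holds two or more foreground
#' pixels that are not 8-connected to each other within that neighbourhood),
#' *fill* (isolated interior holes, as in [fill_isolated()]), then *spur
#' removal*
#' (iteratively delete foreground pixels with exactly one 8-connected
#' foreground neighbour, `spur_iter` times).
#'
#' @param mask logical matrix.
#' @param spur_iter spur-removal iterations.
#' @return logical matrix.
#' @export
morph_postprocess <- function(mask, spur_iter = 3L) {
  mask <- as_mask(mask)
  cfg <- neighbor_config(mask)
  bridged <- mask | (!mask & bridge_lut()[cfg + 1])
  out <- fill_isolated(bridged)
  for (i in seq_len(spur_iter)) {
    endpoints <- out & neighbor_count8(out) == 1L
    if (!any(endpoints)) break
    out <- out & !endpoints
  }
  out
}

#' Vessel orientation inside a window
#'
#' Principal-axis orientation of the foreground pixels from second-order
#' central moments, in degrees in `[0, 180)` measured from the +column axis
#' with rows increasing downward (0 = horizontal, 90 = vertical). Undefined
#' (returns `NULL`) when fewer than `min_px` vessel pixels are present or the
#' moments are isotropic within tolerance.
#'
#' @param mask_window logical matrix (nominally 35 x 35; smaller at borders).
#' @param min_px minimum vessel pixels for a defined orientation.
#' @param tol isotropy tolerance on the normalised moment anisotropy.
#' @return list `(orientation, n_vessel_px)` or `NULL`.
#' @export
window_orientation <- function(mask_window, min_px = 10L, tol = 1e-6) {
  idx <- which(mask_window, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < min_px) return(NULL)
  y <- idx[, 1] - mean(idx[, 1])   # rows, downward
  x <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  if (sqrt((mu20 - mu02)^2 + 4 * mu11^2) < tol * max(mu20 + mu02, 1))
    return(NULL)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (ang < 0) ang <- ang + 180
  if (ang >= 180) ang <- ang - 180
  list(orientation = ang, n_vessel_px = n)
}

#' Orientation-guided region growing
#'
#' Closes flow- or noise-induced gaps in the vessel network. The mask is
#' tiled into `window x window` blocks; in each block with a defined vessel
#' orientation, every endpoint (foreground pixel with exactly one 8-connected
#' neighbour) is extended one pixel at a time along both senses of the block
#' orientation. A pixel is accepted iff its gray level lies within
#' `mean +/- band_factor * sd` of the block's vessel-pixel gray levels;
#' growth stops at the first rejection, when an existing vessel pixel is
#' reached, or after `max_steps` steps. The result always contains the input.
#'
#' @param mask combined vessel mask (logical matrix).
#' @param gray the adjusted mean frame the segmentation consumed.
#' @param window block edge length, pixels.
#' @param max_steps growth cap per endpoint and sense.
#' @param band_factor half-width of the gray acceptance band in SDs.
#' @return logical matrix containing `mask`.
#' @export
region_grow <- function(mask, gray, window = 35L, max_steps = 10L,
                        band_factor = 0.5) {
  mask <- as_mask(mask)
  stopifnot(all(dim(mask) == dim(gray)))
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  nc <- neighbor_count8(mask)
  for (r0 in seq(1, h, by = window)) {
    r1 <- min(r0 + window - 1, h)
    for (c0 in seq(1, w, by = window)) {
      c1 <- min(c0 + window - 1, w)
      sub <- mask[r0:r1, c0:c1, drop = FALSE]
      ws <- window_orientation(sub)
      if (is.null(ws)) next
      gvals <- gray[r0:r1, c0:c1][sub]
      m <- mean(gvals); s <- sd(gvals)
      lo <- m - band_factor * s; hi <- m + band_factor * s
      ep <- which(sub & (nc[r0:r1, c0:c1, drop = FALSE] == 1L),
                  arr.ind = TRUE)
      if (nrow(ep) == 0) next
      a <- ws$orientation * pi / 180
      for (k in seq_len(nrow(ep))) {
        for (sense in c(1, -1)) {
          dy <- sin(a) * sense; dx <- cos(a) * sense
          pos <- c(ep[k, 1] + r0 - 1, ep[k, 2] + c0 - 1)
          cont <- as.numeric(pos)
          for (step in seq_len(max_steps)) {
            cont <- cont + c(dy, dx)
            cand <- round(cont)
            if (all(cand == pos)) next
            if (cand[1] < 1 || cand[1] > h || cand[2] < 1 || cand[2] > w) break
            if (out[cand[1], cand[2]]) break
            g <- gray[cand[1], cand[2]]
            if (is.na(s) || s == 0) { if (g != m) break } else
              if (g < lo || g > hi) break
            out[cand[1], cand[2]] <- TRUE
            pos <- cand
          }
        }
      }
    }
  }
  out
}
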