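# Shared fixtures, all generated in code.

# deterministic smooth static texture frame (stabilization test-bed)
textured_frame <- function(h = 120, w = 160, seed = 42, sd = 0.1) {
  set.seed(seed)
  g <- exp(-(-9:9)^2 / (2 * 3^2)); g <- g / sum(g)
  tex <- capdens:::.sep_filter_cpp(matrix(rnorm(h * w), h, w), g, g)
  pmin(pmax(0.5 + tex / sd(tex) * sd, 0), 1)
}

# repeat a frame with injected cumulative integer shifts (edge replication)
shifted_stack <- function(frame, shifts) {
  lapply(seq_len(nrow(shifts)), function(t)
    capdens:::shift_mat(frame, shifts[t, 1], shifts[t, 2]))
}

# the printed 9x9 toy: bright background with a dark 3-px vertical band
band_frame <- function(h = 9, w = 9, cols = 4:6, bg = 0.8, fg = 0.4) {
  m <- matrix(bg, h, w)
  m[, cols] <- fg
  m
}

# brute-force EDT distances (all-pairs minimum)
edt_bruteforce <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  out
}

# small quick phantom for pipeline-level tests
quick_phantom <- function(seed, ...) {
  phantom_spec(seed = seed, height = 160, width = 220, ...)
}
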