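# Shared small helpers (internal).

# Integer translation with edge replication: content moves by (dy, dx),
# i.e. out[i, j] = m[i - dy, j - dx] with indices clamped to the frame.
shift_mat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[ri, ci, drop = FALSE]
}

as_mask <- function(m) {
  if (is.logical(m)) return(m)
  storage.mode(m) <- "logical"
  m
}

check_same_shape <- function(masks) {
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape error: inputs differ in size", call. = FALSE)
  invisible(dims[, 1])
}

# Rectangular region of interest, 1-based inclusive bounds.
roi_rect <- function(row0, row1, col0, col1) {
  r <- as.integer(c(row0, row1, col0, col1))
  if (anyNA(r) || r[1] > r[2] || r[3] > r[4] || r[1] < 1 || r[3] < 1)
    stop("parameter error: empty or invalid roi", call. = FALSE)
  names(r) <- c("row0", "row1", "col0", "col1")
  r
}

roi_crop <- function(m, roi) m[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]

roi_area <- function(roi) (roi[[2]] - roi[[1]] + 1) * (roi[[4]] - roi[[3]] + 1)

# 8-neighbour foreground count (edge-replicated shifts do not wrap, borders
# handled by zero-padding semantics: out-of-frame neighbours count 0).
neighbor_count8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  z <- matrix(0L, h, w)
  m <- matrix(as.integer(mask), h, w)
  acc <- z
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- z
    rs <- max(1, 1 + dy):min(h, h + dy)
    cs <- max(1, 1 + dx):min(w, w + dx)
    sh[rs, cs] <- m[rs - dy, cs - dx]
    acc <- acc + sh
  }
  acc
}
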