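# toy geometry built in code, shared across tests

# axis-aligned rectangle mask (1-based inclusive bounds)
rect_mask <- function(nr, nc, r1, r2, c1, c2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# disk mask with centre (row, col) 1-based and radius in px
disk_mask <- function(nr, nc, centre, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
}

# exact Euclidean-disk dilation, brute force: the independent oracle for the
# morphology used in region prediction
dilate_oracle <- function(mask, radius) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  rr <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cc <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  for (i in seq_len(nrow(idx))) {
    out <- out | ((rr - idx[i, 1])^2 + (cc - idx[i, 2])^2 <= radius^2)
  }
  out
}

# lens (intersection of two disks) with horizontal corners at
# (row0, col0 +- half_width), half-thickness tau; returns mask
lens_mask <- function(nr, nc, row0, col0, half_width, tau) {
  R <- (half_width^2 / tau + tau) / 2
  d <- R - tau
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  abs(cc - col0) <= half_width &
    (abs(rr - row0) + d)^2 <= pmax(R^2 - (cc - col0)^2, 0)
}

# rectangle with two semicircular notches cut into its top edge; returns the
# mask and the analytic notch-bottom coordinates (x, y) 0-based
notched_rect <- function(nr = 80, nc = 120, top = 30, bottom = 66,
                         left = 15, right = 105, notch_cols = c(45, 75),
                         notch_r = 10) {
  m <- rect_mask(nr, nc, top, bottom, left, right)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (ncol0 in notch_cols)
    m <- m & !((rr - top)^2 + (cc - ncol0)^2 <= notch_r^2)
  list(mask = m,
       bottoms = cbind(x = notch_cols - 1, y = top - 1 + notch_r))
}

# labeled two-bone toy slice: notched femur rectangle below, patella lens
# above, separated by `gap` pixels
toy_slice <- function(gap = 6, nr = 100, nc = 100) {
  lab <- matrix(0L, nr, nc)
  fem <- notched_rect(nr, nc, top = 60, bottom = 85, left = 20, right = 80,
                      notch_cols = c(38, 62), notch_r = 7)
  lab[fem$mask] <- 1L
  lab[lens_mask(nr, nc, 60 - gap - 8, 50, 20, 7)] <- 2L
  lab
}

# one-pixel erosion (4-neighbourhood), brute force
erode_1px <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- mask[c(1, seq_len(nr - 1)), ]
  down <- mask[c(seq_len(nr)[-1], nr), ]
  left <- mask[, c(1, seq_len(nc - 1))]
  right <- mask[, c(seq_len(nc)[-1], nc)]
  mask & up & down & left & right
}
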