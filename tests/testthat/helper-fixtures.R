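# Programmatic fixtures shared across test files.

# Rasterize an analytic ellipse (semi-axes in pixels, orientation in degrees
# from the x axis) into a cell_mask. Used as the independent construction
# oracle for the moment-ellipse fit.
rasterize_ellipse <- function(a_px, b_px, theta_deg = 0, shape = c(256L, 256L),
                              pixel_size = 0.5, stretch_axis = "x") {
  nr <- shape[1]; nc <- shape[2]
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  y <- matrix(seq_len(nr), nr, nc) - cy
  th <- theta_deg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  cell_mask((u / a_px)^2 + (v / b_px)^2 <= 1, pixel_size = pixel_size,
            stretch_axis = stretch_axis)
}

make_disc <- function(r_um = 25, pixel_size = 0.5, shape = c(256L, 256L)) {
  make_initial_cell(r_um, 0, pixel_size, shape)
}

# Small random single-component blob for brute-force comparisons.
random_blob <- function(seed, shape = c(64L, 64L), pixel_size = 1) {
  make_initial_cell(radius = 12, irregularity = 0.25, pixel_size = pixel_size,
                    image_shape = shape, seed = seed)
}

# Brute-force per-pixel quadrant classifier implementing the sector
# definition directly (independent of partition_quadrants internals).
brute_quadrant <- function(mask) {
  px <- mask$pixels
  ps <- mask$pixel_size
  idx <- which(px, arr.ind = TRUE)
  cx <- mean((idx[, 2] - 0.5) * ps); cy <- mean((idx[, 1] - 0.5) * ps)
  out <- matrix(NA_character_, nrow(px), ncol(px))
  for (i in seq_len(nrow(px))) {
    for (j in seq_len(ncol(px))) {
      du <- (j - 0.5) * ps - cx
      dv <- (i - 0.5) * ps - cy
      out[i, j] <- if (du >= abs(dv) && du > 0) "axial_plus"
        else if (-du >= abs(dv) && du < 0) "axial_minus"
        else if (dv > abs(du)) "transverse_plus"
        else if (dv < -abs(du)) "transverse_minus"
        else "axial_plus"
    }
  }
  out
}

# Draw a block-filled fiducial grid directly (no bead rendering): full
# control over square placement for detector edge-case tests.
draw_block_grid <- function(centers_um, side_um, shape, pixel_size) {
  img <- matrix(0, shape[1], shape[2])
  h <- side_um / 2
  for (k in seq_len(nrow(centers_um))) {
    cx <- centers_um[k, 1]; cy <- centers_um[k, 2]
    cols <- max(1, round((cx - h) / pixel_size)):min(shape[2], round((cx + h) / pixel_size))
    rows <- max(1, round((cy - h) / pixel_size)):min(shape[1], round((cy + h) / pixel_size))
    img[rows, cols] <- 1
  }
  micropattern_image(img, pixel_size)
}

a_later <- function(m) { m$time <- m$time + 1; m }
f1_at <- function(m, t) { m$time <- t; m }
find_cycle_phase <- function(frames, cyc, phase) {
  Filter(function(f) f$cycle_index == cyc && f$phase_tag == phase, frames)[[1]]
}
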