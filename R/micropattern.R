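#' Specify a square fiducial micropattern grid
#'
#' Geometry of the microcontact-printed fiducial grid used to visualize
#' substrate strain: bright squares of side `square_side` placed on a
#' lattice of pitch `pitch`. Defaults follow the standard pattern of
#' 50 x 50 um squares spaced 50 um apart (100 um center-to-center pitch).
#'
#' @param square_side square edge length, um.
#' @param pitch center-to-center lattice spacing, um; must exceed
#'   `square_side`.
#' @param n_rows,n_cols grid dimensions.
#' @return list of class `grid_spec`.
#' @export
grid_spec <- function(square_side = 50, pitch = 100, n_rows = 6, n_cols = 6) {
  if (pitch <= square_side) stopf("configuration error: pitch must exceed square_side")
  if (n_rows < 2 || n_cols < 2) stopf("configuration error: grid must be at least 2x2")
  structure(list(square_side = square_side, pitch = pitch,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Construct a micropattern image object
#'
#' @param pixels non-negative intensity matrix.
#' @param pixel_size um per pixel.
#' @param grid_spec the [grid_spec()] that generated the pattern (or NULL
#'   for imported images).
#' @param applied_strain numeric c(eps_ax, eps_tr) ground-truth strain.
#' @return object of class `micropattern_image`.
#' @export
micropattern_image <- function(pixels, pixel_size, grid_spec = NULL,
                               applied_strain = c(0, 0)) {
  if (!is.matrix(pixels) || any(pixels < 0)) {
    stopf("input error: pixels must be a non-negative matrix")
  }
  if (pixel_size <= 0) stopf("input error: pixel_size must be > 0")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 grid_spec = grid_spec,
                 applied_strain = c(eps_ax = applied_strain[1],
                                    eps_tr = applied_strain[2])),
            class = "micropattern_image")
}

#' Render a synthetic micropattern fiducial image
#'
#' Renders the fiducial grid as bead fluorescence: each square is filled
#' with a dense lattice of sub-resolution beads (one per square micrometre,
#' with small seeded placement jitter); bead positions are mapped by the
#' affine substrate strain about the image center, perturbed by Gaussian
#' localization noise of `bead_noise_sigma`, splatted bilinearly, and
#' blurred with a diffraction-like Gaussian PSF. Squares therefore render
#' brighter than the (zero) background. The frame size is fixed by the grid
#' geometry plus margin for strains up to 25%, independent of the applied
#' strain.
#'
#' @param spec a [grid_spec()].
#' @param eps_ax,eps_tr applied engineering strains (axial = image x).
#' @param bead_noise_sigma bead localization noise, um.
#' @param pixel_size um per pixel.
#' @param seed integer seed (bead jitter and localization noise).
#' @param psf_sigma Gaussian PSF sigma, um.
#' @return a [micropattern_image()].
#' @export
make_micropattern <- function(spec = grid_spec(), eps_ax = 0, eps_tr = 0,
                              bead_noise_sigma = 0, pixel_size = 0.5,
                              seed = 1L, psf_sigma = 0.4) {
  stopifnot(inherits(spec, "grid_spec"))
  if (eps_ax <= -1 || eps_tr <= -1) stopf("input error: strains must be > -1")
  ext_x <- (spec$n_cols - 1) * spec$pitch + spec$square_side
  ext_y <- (spec$n_rows - 1) * spec$pitch + spec$square_side
  w_um <- ext_x * 1.25 + spec$pitch
  h_um <- ext_y * 1.25 + spec$pitch
  nc <- ceiling(w_um / pixel_size); nr <- ceiling(h_um / pixel_size)
  cx <- nc * pixel_size / 2; cy <- nr * pixel_size / 2

  ## unstrained bead positions: ~1 bead per um^2 inside each square
  nb_side <- max(2L, round(spec$square_side))
  off <- (seq_len(nb_side) - (nb_side + 1) / 2) / nb_side * spec$square_side
  bx0 <- cx + (seq_len(spec$n_cols) - (spec$n_cols + 1) / 2) * spec$pitch
  by0 <- cy + (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$pitch
  centers <- expand.grid(x = bx0, y = by0)
  beads_x <- rep(centers$x, each = nb_side^2) + rep(rep(off, nb_side), nrow(centers))
  beads_y <- rep(centers$y, each = nb_side^2) + rep(rep(off, each = nb_side), nrow(centers))

  with_seed(derive_seed(seed, 7), {
    jit <- spec$square_side / nb_side * 0.25
    beads_x <- beads_x + stats::runif(length(beads_x), -jit, jit)
    beads_y <- beads_y + stats::runif(length(beads_y), -jit, jit)
  })
  ## affine substrate map about the image center, then localization noise
  beads_x <- cx + (1 + eps_ax) * (beads_x - cx)
  beads_y <- cy + (1 + eps_tr) * (beads_y - cy)
  if (bead_noise_sigma > 0) {
    with_seed(derive_seed(seed, 11), {
      beads_x <- beads_x + stats::rnorm(length(beads_x), 0, bead_noise_sigma)
      beads_y <- beads_y + stats::rnorm(length(beads_y), 0, bead_noise_sigma)
    })
  }

  ## bilinear splat onto the pixel raster
  gx <- beads_x / pixel_size + 0.5   # in pixel-center units
  gy <- beads_y / pixel_size + 0.5
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  img <- matrix(0, nr, nc)
  for (corner in list(list(x0, y0, (1 - fx) * (1 - fy)),
                      list(x0 + 1, y0, fx * (1 - fy)),
                      list(x0, y0 + 1, (1 - fx) * fy),
                      list(x0 + 1, y0 + 1, fx * fy))) {
    xi <- corner[[1]]; yi <- corner[[2]]; w <- corner[[3]]
    ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr & w > 0
    if (any(ok)) {
      lin <- (xi[ok] - 1) * nr + yi[ok]
      agg <- rowsum(w[ok], lin)
      img[as.integer(rownames(agg))] <- img[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  if (psf_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = psf_sigma / pixel_size))
  }
  img <- pmax(img, 0)
  if (max(img) > 0) img <- img / max(img)
  micropattern_image(img, pixel_size, spec, c(eps_ax, eps_tr))
}

#' @export
print.micropattern_image <- function(x, ...) {
  cat(sprintf("micropattern_image %dx%d px (%.3g um/px), strain (%.4f, %.4f)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$applied_strain[1], x$applied_strain[2]))
  invisible(x)
}
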