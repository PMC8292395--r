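#' Construct a cell mask frame
#'
#' A `cell_mask` is one binary cell silhouette with pixel calibration and
#' cycle-phase annotation — the atom of all shape measurements. The
#' foreground must be a single nonempty 4-connected component that does not
#' touch the image border. Image convention: matrices are indexed
#' `[row, col]`; the x axis runs along columns and the y axis along rows;
#' `stretch_axis = "x"` means the applied strain acts along columns.
#'
#' @param pixels logical (or 0/1) matrix, `TRUE` = cell.
#' @param pixel_size pixel edge length in micrometres.
#' @param time acquisition time in seconds from experiment start.
#' @param cycle_index stretch-cycle index the frame belongs to (0 = before
#'   stretching starts).
#' @param phase_tag one of `"pre_stretch"`, `"during_stretch"`,
#'   `"post_release"`, `"relaxation_end"`.
#' @param stretch_axis `"x"` or `"y"`: image axis of the applied strain.
#' @param check validate the single-component/border invariants (default TRUE).
#' @return an object of class `cell_mask`.
#' @export
cell_mask <- function(pixels, pixel_size, time = 0, cycle_index = 0L,
                      phase_tag = "pre_stretch", stretch_axis = "x",
                      check = TRUE) {
  if (!is.matrix(pixels)) stopf("input error: pixels must be a matrix")
  px <- if (is.logical(pixels)) pixels else pixels > 0.5
  if (!is_number(pixel_size) || pixel_size <= 0) {
    stopf("input error: pixel_size must be > 0")
  }
  if (!phase_tag %in% phase_tags) {
    stopf("input error: unknown phase_tag '%s'", phase_tag)
  }
  if (!stretch_axis %in% c("x", "y")) {
    stopf("input error: stretch_axis must be 'x' or 'y'")
  }
  m <- structure(
    list(pixels = px, pixel_size = pixel_size, time = time,
         cycle_index = as.integer(cycle_index), phase_tag = phase_tag,
         stretch_axis = stretch_axis),
    class = "cell_mask")
  if (check) validate_mask(m)
  m
}

validate_mask <- function(mask) {
  px <- mask$pixels
  if (!any(px)) stopf("input error: mask foreground is empty")
  if (any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) || any(px[, ncol(px)])) {
    stopf("input error: mask foreground touches the image border")
  }
  lab <- EBImage::bwlabel(px * 1)
  if (max(lab) != 1L) {
    stopf("input error: mask has %d connected components (expected 1)", max(lab))
  }
  invisible(mask)
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf(
    "cell_mask %dx%d px (%.3g um/px), area %.1f um2, t=%.1f s, cycle %d [%s], stretch axis %s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    sum(x$pixels) * x$pixel_size^2, x$time, x$cycle_index, x$phase_tag,
    x$stretch_axis))
  invisible(x)
}

## Pixel-center coordinates (micrometres) of every pixel of an nr x nc frame.
## Returns list(x, y) of matrices the same shape as the frame.
pixel_coords_um <- function(nr, nc, pixel_size) {
  list(x = matrix((seq_len(nc) - 0.5) * pixel_size, nr, nc, byrow = TRUE),
       y = matrix((seq_len(nr) - 0.5) * pixel_size, nr, nc))
}

#' Generate a near-circular initial cell mask
#'
#' Rasterizes a disc of the given radius whose boundary radius is perturbed
#' by a smooth random function of the polar angle (low-order Fourier modes,
#' seeded), emulating a well-spread epithelial cell of high circularity.
#' With `irregularity = 0` the mask is an exact rasterized disc.
#'
#' @param radius nominal cell radius in micrometres.
#' @param irregularity relative amplitude of the smooth radius perturbation
#'   (0 = perfect disc). Values around 0.05–0.10 give gently anisotropic
#'   cells with randomly oriented long axes.
#' @param pixel_size micrometres per pixel.
#' @param image_shape integer c(rows, cols) of the frame.
#' @param seed integer seed for the perturbation.
#' @param stretch_axis image axis of the applied strain, `"x"` or `"y"`.
#' @return a [cell_mask()] centred in the frame.
#' @export
make_initial_cell <- function(radius, irregularity = 0, pixel_size = 0.5,
                              image_shape = c(512L, 512L), seed = 1L,
                              stretch_axis = "x") {
  if (!is_number(radius) || radius <= 0) stopf("input error: radius must be > 0")
  nr <- image_shape[1]; nc <- image_shape[2]
  max_r <- radius * (1 + max(0, irregularity) * 2)
  if (2 * max_r >= (min(nr, nc) - 4) * pixel_size) {
    stopf("dimension error: radius %.1f um does not fit in a %dx%d frame at %.3g um/px",
          radius, nr, nc, pixel_size)
  }
  co <- pixel_coords_um(nr, nc, pixel_size)
  cx <- nc * pixel_size / 2; cy <- nr * pixel_size / 2
  dx <- co$x - cx; dy <- co$y - cy
  r <- sqrt(dx^2 + dy^2)
  if (irregularity > 0) {
    modes <- 2:5
    coef <- with_seed(seed, list(a = stats::rnorm(length(modes)) / modes,
                                 b = stats::rnorm(length(modes)) / modes))
    phi <- atan2(dy, dx)
    s <- 0
    for (i in seq_along(modes)) {
      s <- s + coef$a[i] * cos(modes[i] * phi) + coef$b[i] * sin(modes[i] * phi)
    }
    rb <- radius * pmax(0.5, 1 + irregularity * s)
  } else {
    rb <- radius
  }
  cell_mask(r <= rb, pixel_size = pixel_size, time = 0, cycle_index = 0L,
            phase_tag = "pre_stretch", stretch_axis = stretch_axis)
}

## Bilinear inverse-mapped affine scaling of a numeric matrix about the image
## center: output(x, y) = input(cx + (x - cx)/sx, cy + (y - cy)/sy).
## Out-of-range samples return `fill`.
affine_scale_matrix <- function(m, sx, sy, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  xs <- cx + (seq_len(nc) - cx) / sx   # source column per output column
  ys <- cy + (seq_len(nr) - cy) / sy   # source row per output row
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  X0 <- cl(x0, nc); X1 <- cl(x0 + 1, nc)
  Y0 <- cl(y0, nr); Y1 <- cl(y0 + 1, nr)
  ok_x <- xs >= 1 & xs <= nc
  ok_y <- ys >= 1 & ys <= nr
  out <-(m[Y0, X0, drop = FALSE] * tcrossprod(1 - fy, 1 - fx) +
          m[Y0, X1, drop = FALSE] * tcrossprod(1 - fy, fx) +
          m[Y1, X0, drop = FALSE] * tcrossprod(fy, 1 - fx) +
          m[Y1, X1, drop = FALSE] * tcrossprod(fy, fx))
  out[!ok_y, ] <- fill
  out[, !ok_x] <- fill
  out
}

#' Apply an affine substrate strain to a frame
#'
#' Pure affine scaling about the image center: lengths scale by
#' `(1 + eps_ax)` along the stretch axis and `(1 + eps_tr)` transverse to it.
#' Binary masks are resampled bilinearly and re-binarized at 0.5; intensity
#' images are resampled bilinearly. The map is invertible to within
#' resampling error via `eps' = 1/(1+eps) - 1`.
#'
#' @param frame a [cell_mask()] or [micropattern_image()].
#' @param eps_ax axial engineering strain, `> -1`.
#' @param eps_tr transverse engineering strain, `> -1`.
#' @return object of the same class as `frame`.
#' @export
apply_substrate_strain <- function(frame, eps_ax, eps_tr) {
  if (!is_number(eps_ax) || eps_ax <= -1 || !is_number(eps_tr) || eps_tr <= -1) {
    stopf("input error: strains must be > -1")
  }
  UseMethod("apply_substrate_strain")
}

#' @export
apply_substrate_strain.cell_mask <- function(frame, eps_ax, eps_tr) {
  if (eps_ax == 0 && eps_tr == 0) return(frame)
  if (frame$stretch_axis == "x") {
    sx <- 1 + eps_ax; sy <- 1 + eps_tr
  } else {
    sx <- 1 + eps_tr; sy <- 1 + eps_ax
  }
  out <- affine_scale_matrix(frame$pixels * 1, sx, sy)
  frame$pixels <- out >= 0.5
  frame
}

#' @export
apply_substrate_strain.micropattern_image <- function(frame, eps_ax, eps_tr) {
  if (eps_ax == 0 && eps_tr == 0) return(frame)
  ## stretch axis for micropattern images is x by convention
  out <- affine_scale_matrix(frame$pixels, 1 + eps_ax, 1 + eps_tr)
  frame$pixels <- pmax(out, 0)
  frame$applied_strain <- c(eps_ax = unname(frame$applied_strain[1] + eps_ax),
                            eps_tr = unname(frame$applied_strain[2] + eps_tr))
  frame
}
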