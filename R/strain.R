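## Split sorted 1-D positions into clusters separated by gaps > min_sep.
cluster_1d <- function(v, min_sep) {
  o <- order(v)
  sv <- v[o]
  grp <- cumsum(c(1, diff(sv) > min_sep))
  means <- tapply(sv, grp, mean)
  list(group_of = grp[order(o)], means = as.numeric(means))
}

#' Detect the fiducial square grid in a micropattern image
#'
#' Segments the bright squares by automatic (Otsu) thresholding and
#' connected-component labeling, rejects components that touch the image
#' border or whose area deviates more than 50% from the component median,
#' and reports per-square centroids and axis-aligned extents plus the mean
#' lattice pitches. Centers are sorted row-major.
#'
#' @param image a [micropattern_image()].
#' @return list of class `grid_fit`: `centers` (n x 2 matrix, um, columns
#'   x/y), `side_ax`, `side_tr` (mean extents along/across the stretch
#'   axis, um), `pitch_ax`, `pitch_tr` (mean center spacings, um),
#'   `n_detected`.
#' @export
detect_grid <- function(image) {
  stopifnot(inherits(image, "micropattern_image"))
  px <- image$pixels
  ps <- image$pixel_size
  if (max(px) <= min(px)) stopf("detection error: 0 squares detected (blank image)")
  norm <- px / max(px)
  th <- EBImage::otsu(EBImage::Image(norm))
  bin <- norm > th
  lab <- EBImage::bwlabel(bin * 1)
  ncomp <- max(lab)
  if (ncomp < 1) stopf("detection error: 0 squares detected")
  nr <- nrow(px); nc <- ncol(px)
  keep <- logical(ncomp)
  feats <- vector("list", ncomp)
  border_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  areas <- tabulate(lab[lab > 0], nbins = ncomp)
  med_area <- stats::median(areas)
  for (i in seq_len(ncomp)) {
    if (i %in% border_ids) next
    if (abs(areas[i] - med_area) > 0.5 * med_area) next
    keep[i] <- TRUE
  }
  ids <- which(keep)
  if (length(ids) < 4) {
    stopf("detection error: only %d usable squares detected (need >= 4)", length(ids))
  }
  cen <- matrix(NA_real_, length(ids), 2, dimnames = list(NULL, c("x", "y")))
  ext <- matrix(NA_real_, length(ids), 2)
  for (k in seq_along(ids)) {
    w <- which(lab == ids[k], arr.ind = TRUE)
    cen[k, ] <- c(mean(w[, 2] - 0.5), mean(w[, 1] - 0.5)) * ps
    ext[k, ] <- c(diff(range(w[, 2])) + 1, diff(range(w[, 1])) + 1) * ps
  }
  min_sep <- med_area^0.5 * ps / 2   # half a square side: safe for pitch > side
  colc <- cluster_1d(cen[, "x"], min_sep)
  rowc <- cluster_1d(cen[, "y"], min_sep)
  ord <- order(rowc$group_of, cen[, "x"])
  pitch_x <- if (length(colc$means) > 1) mean(diff(sort(colc$means))) else NA_real_
  pitch_y <- if (length(rowc$means) > 1) mean(diff(sort(rowc$means))) else NA_real_
  structure(list(centers = cen[ord, , drop = FALSE],
                 side_ax = mean(ext[, 1]), side_tr = mean(ext[, 2]),
                 pitch_ax = pitch_x, pitch_tr = pitch_y,
                 n_detected = length(ids)),
            class = "grid_fit")
}

#' @export
print.grid_fit <- function(x, ...) {
  cat(sprintf(
    "grid_fit: %d squares; side %.2f x %.2f um; pitch %.2f x %.2f um\n",
    x$n_detected, x$side_ax, x$side_tr, x$pitch_ax, x$pitch_tr))
  invisible(x)
}

new_strain_measurement <- function(eps_ax, eps_tr) {
  ratio <- if (abs(eps_ax) > 1e-6) abs(eps_tr) / abs(eps_ax) else NA_real_
  structure(list(eps_ax = eps_ax, eps_tr = eps_tr, ratio = ratio),
            class = "strain_measurement")
}

#' Measure substrate strain from a grid pair
#'
#' Engineering strains recovered from the change in lattice pitch between a
#' reference and a deformed grid fit:
#' `eps_ax = (pitch_ax' - pitch_ax) / pitch_ax`, and analogously transverse.
#' Pitch (center spacing) is used rather than square side lengths because it
#' is insensitive to threshold bias; the side-based extents in
#' [detect_grid()] serve as a cross-check. Both fits must come from the same
#' grid layout.
#'
#' @param ref [detect_grid()] fit of the reference (unstrained) image.
#' @param stretched fit of the deformed image.
#' @return list of class `strain_measurement`: `eps_ax`, `eps_tr`, `ratio`
#'   (= |eps_tr|/|eps_ax|, NA when `eps_ax` is ~0).
#' @export
measure_strain <- function(ref, stretched) {
  stopifnot(inherits(ref, "grid_fit"), inherits(stretched, "grid_fit"))
  if (ref$n_detected != stretched$n_detected) {
    stopf("pairing error: grids have %d vs %d squares", ref$n_detected,
          stretched$n_detected)
  }
  if (is.na(ref$pitch_ax) || is.na(ref$pitch_tr)) {
    stopf("pairing error: reference grid has no measurable pitch")
  }
  new_strain_measurement((stretched$pitch_ax - ref$pitch_ax) / ref$pitch_ax,
                         (stretched$pitch_tr - ref$pitch_tr) / ref$pitch_tr)
}

#' Residual substrate strain after relaxation
#'
#' Same computation as [measure_strain()] applied to a before-stretching /
#' after-relaxation image pair; quantifies how completely an elastic
#' substrate returns to its rest shape. Summaries report the magnitude in
#' percent.
#'
#' @param ref fit of the image before cyclic stretching.
#' @param relaxed fit after release and full relaxation.
#' @return a `strain_measurement` (see [measure_strain()]).
#' @export
residual_strain <- function(ref, relaxed) {
  measure_strain(ref, relaxed)
}

#' @export
print.strain_measurement <- function(x, ...) {
  cat(sprintf("strain: eps_ax = %.4f (%.2f%%), eps_tr = %.4f (%.2f%%), |tr|/|ax| = %s\n",
              x$eps_ax, 100 * x$eps_ax, x$eps_tr, 100 * x$eps_tr,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio))))
  invisible(x)
}

#' Linear regression of measured against commanded strain
#'
#' Ordinary least squares of the measured axial and transverse strains on
#' the commanded axial strain, per axis, quantifying substrate strain
#' linearity. The transverse fit uses strain magnitudes.
#'
#' @param commanded numeric vector of commanded axial strains (>= 3 values).
#' @param measured list of [measure_strain()] results, same length.
#' @return list with elements `axial` and `transverse`, each
#'   `c(slope, intercept, r_squared)`.
#' @export
strain_linearity <- function(commanded, measured) {
  if (length(commanded) != length(measured)) {
    stopf("input error: commanded and measured lengths differ")
  }
  if (length(commanded) < 3) stopf("input error: need >= 3 strain points")
  ax <- vapply(measured, function(m) m$eps_ax, numeric(1))
  tr <- vapply(measured, function(m) abs(m$eps_tr), numeric(1))
  fit1 <- function(y) {
    f <- stats::lm(y ~ commanded)
    r2 <- if (stats::var(y) > 0) summary(f)$r.squared else NA_real_
    c(slope = unname(stats::coef(f)[2]), intercept = unname(stats::coef(f)[1]),
      r_squared = r2)
  }
  list(axial = fit1(ax), transverse = fit1(tr))
}
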