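#' Fit the moment-equivalent ellipse of a cell mask
#'
#' Computes the ellipse with the same area-normalized second central moments
#' as the filled mask (the standard equivalent-ellipse definition). The
#' orientation `theta` is the angle, in degrees within (-90, 90], between the
#' ellipse major axis and the stretch axis of the mask. For nearly circular
#' masks (eccentricity < 0.01) the orientation is undefined and reported as 0
#' by tie-break.
#'
#' @param mask a [cell_mask()].
#' @return list of class `ellipse_fit`: `centroid` (x, y, um), `major`,
#'   `minor` (full axis lengths, um), `theta` (degrees from stretch axis),
#'   `eccentricity`, `stretch_axis`.
#' @export
fit_ellipse <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (!any(px)) stopf("input error: empty mask")
  idx <- which(px, arr.ind = TRUE)
  ps <- mask$pixel_size
  ## coordinate along stretch axis (u) and transverse (v), in um
  xs <- (idx[, 2] - 0.5) * ps
  ys <- (idx[, 1] - 0.5) * ps
  if (mask$stretch_axis == "x") { u <- xs; v <- ys } else { u <- ys; v <- xs }
  mu <- mean(u); mv <- mean(v)
  du <- u - mu; dv <- v - mv
  ## + ps^2/12: second moment of the square pixel footprint itself
  m20 <- mean(du^2) + ps^2 / 12
  m02 <- mean(dv^2) + ps^2 / 12
  m11 <- mean(du * dv)
  tr <- m20 + m02
  det_ <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  l1 <- tr / 2 + det_      # variance along major axis
  l2 <- tr / 2 - det_
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  theta <- if (ecc < 0.01) 0 else {
    th <- 0.5 * atan2(2 * m11, m20 - m02) * 180 / pi
    if (th <= -90) th <- th + 180
    if (th > 90) th <- th - 180
    th
  }
  structure(
    list(centroid = c(x = mean(xs), y = mean(ys)), major = major,
         minor = minor, theta = theta, eccentricity = ecc,
         stretch_axis = mask$stretch_axis),
    class = "ellipse_fit")
}

#' Orientation index cos(2*theta)
#'
#' The orientation index of a fitted cell ellipse: `cos(2*theta_ref)` with
#' `theta_ref` the major-axis angle measured from the chosen reference axis.
#' With the default `reference = "stretch_axis"` the index is +1 for a cell
#' perfectly aligned with the direction of stretching and -1 for a cell
#' perpendicular to it; `reference = "transverse_axis"` flips the sign, which
#' matches time-course plots that report transverse alignment as positive.
#'
#' @param fit an [fit_ellipse()] result.
#' @param reference `"stretch_axis"` (default) or `"transverse_axis"`.
#' @return dimensionless index in `[-1, 1]`.
#' @export
orientation_index <- function(fit, reference = c("stretch_axis", "transverse_axis")) {
  stopifnot(inherits(fit, "ellipse_fit"))
  reference <- match.arg(reference)
  th <- fit$theta * pi / 180
  oi <- cos(2 * th)
  if (reference == "transverse_axis") oi <- -oi
  oi
}

#' Axis-aligned bounding-rectangle lengths of a cell mask
#'
#' Fits the stretch-axis-aligned bounding rectangle of the cell outline and
#' returns its extent along the stretch (axial) direction and perpendicular
#' (transverse) direction, in micrometres.
#'
#' @param mask a [cell_mask()].
#' @return named numeric: `axial_length`, `transverse_length` (um).
#' @export
fit_rectangle <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (!any(px)) stopf("input error: empty mask")
  rows <- range(which(rowSums(px) > 0))
  cols <- range(which(colSums(px) > 0))
  ext_x <- (cols[2] - cols[1] + 1) * mask$pixel_size
  ext_y <- (rows[2] - rows[1] + 1) * mask$pixel_size
  if (mask$stretch_axis == "x") {
    c(axial_length = ext_x, transverse_length = ext_y)
  } else {
    c(axial_length = ext_y, transverse_length = ext_x)
  }
}

#' Spreading area of a cell mask
#'
#' Foreground pixel count times the pixel area.
#'
#' @param mask a [cell_mask()].
#' @return area in square micrometres.
#' @export
spreading_area <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  if (!any(mask$pixels)) stopf("input error: empty mask")
  sum(mask$pixels) * mask$pixel_size^2
}

#' Shape-metric time course of a frame stack
#'
#' Applies the three morphometrics (orientation index, rectangle lengths,
#' spreading area) to every frame whose phase tag matches `phase_filter`,
#' ordered by time. The default keeps relaxed-state frames only
#' (`pre_stretch` and `relaxation_end`), so the affine distortion of
#' during-stretch frames never contaminates the time course.
#'
#' @param stack list of [cell_mask()] frames.
#' @param phase_filter character vector of phase tags to keep.
#' @param reference reference axis for the orientation index, see
#'   [orientation_index()].
#' @return data.frame: `time`, `cycle`, `phase`, `orientation_index`,
#'   `axial_length`, `transverse_length`, `area`.
#' @export
summarize_timecourse <- function(stack,
                                 phase_filter = c("pre_stretch", "relaxation_end"),
                                 reference = "stretch_axis") {
  if (length(stack) == 0) stopf("input error: empty frame stack")
  keep <- vapply(stack, function(f) f$phase_tag %in% phase_filter, logical(1))
  if (!any(keep)) stopf("input error: no frames match phase filter")
  frames <- stack[keep]
  rows <- lapply(frames, function(f) {
    fit <- fit_ellipse(f)
    rect <- fit_rectangle(f)
    data.frame(time = f$time, cycle = f$cycle_index, phase = f$phase_tag,
               orientation_index = orientation_index(fit, reference),
               axial_length = unname(rect["axial_length"]),
               transverse_length = unname(rect["transverse_length"]),
               area = spreading_area(f))
  })
  out <- do.call(rbind, rows)
  out[order(out$time), , drop = FALSE]
}
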