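#' Signed difference map between consecutive frames
#'
#' Classifies each pixel of a pair of frames as protrusion (+1, area gained),
#' retraction (-1, area lost) or unchanged (0). For binary masks the map is
#' the exact set difference: +1 where the later frame covers a pixel the
#' earlier did not, -1 where cover was lost. For intensity images, pixels
#' whose median-centred intensity change exceeds `+intensity_threshold` /
#' falls below `-intensity_threshold` are labelled +1 / -1.
#'
#' @param frame1 earlier frame: [cell_mask()] or numeric intensity matrix.
#' @param frame2 later frame of the same shape and calibration.
#' @param intensity_threshold positive threshold, required for intensity
#'   input, ignored for binary masks.
#' @return list of class `difference_map`: `labels` (integer matrix in
#'   {-1, 0, +1}), `pixel_size`, `t_pair`.
#' @export
difference_map <- function(frame1, frame2, intensity_threshold = NULL) {
  if (inherits(frame1, "cell_mask") && inherits(frame2, "cell_mask")) {
    if (!identical(dim(frame1$pixels), dim(frame2$pixels))) {
      stopf("input error: frames have different shapes")
    }
    if (frame1$pixel_size != frame2$pixel_size) {
      stopf("input error: frames have different pixel calibration")
    }
    if (frame2$time <= frame1$time) {
      stopf("input error: frame2 must be later than frame1")
    }
    lab <- matrix(0L, nrow(frame1$pixels), ncol(frame1$pixels))
    lab[frame2$pixels & !frame1$pixels] <- 1L
    lab[frame1$pixels & !frame2$pixels] <- -1L
    structure(list(labels = lab, pixel_size = frame1$pixel_size,
                   t_pair = c(frame1$time, frame2$time)),
              class = "difference_map")
  } else if (is.matrix(frame1) && is.matrix(frame2)) {
    if (!identical(dim(frame1), dim(frame2))) {
      stopf("input error: frames have different shapes")
    }
    if (is.null(intensity_threshold)) {
      stopf("configuration error: intensity input requires intensity_threshold")
    }
    d <- frame2 - frame1
    d <- d - stats::median(d)      # background normalization
    lab <- matrix(0L, nrow(d), ncol(d))
    lab[d > intensity_threshold] <- 1L
    lab[d < -intensity_threshold] <- -1L
    structure(list(labels = lab, pixel_size = NA_real_, t_pair = c(NA, NA)),
              class = "difference_map")
  } else {
    stopf("input error: frames must both be cell_mask or both intensity matrices")
  }
}

quadrant_levels <- c("axial_plus", "axial_minus", "transverse_plus", "transverse_minus")

#' Diagonal quadrant partition of a frame at the cell centroid
#'
#' Divides the frame into two axial and two transverse sectors by the two
#' +/-45 degree diagonals through the foreground centroid. A pixel at offset
#' (du, dv) from the centroid (du along the stretch axis) is `axial_plus` if
#' du >= |dv| and du > 0, `axial_minus` if -du >= |dv| and du < 0,
#' `transverse_plus` if dv > |du| and `transverse_minus` if dv < -|du|;
#' diagonal ties go to the axial sectors and the centroid pixel itself to
#' `axial_plus`, so every pixel carries exactly one label.
#'
#' @param mask a [cell_mask()]; the centroid is its foreground
#'   center of mass.
#' @return list of class `quadrant_partition`: `labels` (integer matrix,
#'   1..4 indexing `axial_plus`, `axial_minus`, `transverse_plus`,
#'   `transverse_minus`), `centroid` (x, y in um), `pixel_size`,
#'   `stretch_axis`.
#' @export
partition_quadrants <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  px <- mask$pixels
  if (!any(px)) stopf("input error: empty mask")
  ps <- mask$pixel_size
  idx <- which(px, arr.ind = TRUE)
  cx <- mean((idx[, 2] - 0.5) * ps)
  cy <- mean((idx[, 1] - 0.5) * ps)
  co <- pixel_coords_um(nrow(px), ncol(px), ps)
  if (mask$stretch_axis == "x") {
    du <- co$x - cx; dv <- co$y - cy
  } else {
    du <- co$y - cy; dv <- co$x - cx
  }
  lab <- matrix(0L, nrow(px), ncol(px))
  lab[dv > abs(du)] <- 3L
  lab[dv < -abs(du)] <- 4L
  lab[du >= abs(dv) & du > 0] <- 1L
  lab[-du >= abs(dv) & du < 0] <- 2L
  lab[lab == 0L] <- 1L   # exact-centroid pixels
  structure(list(labels = lab, centroid = c(x = cx, y = cy),
                 pixel_size = ps, stretch_axis = mask$stretch_axis),
            class = "quadrant_partition")
}

#' Per-quadrant net area change, normalized
#'
#' Integrates a signed difference map over the four quadrant sectors and
#' normalizes by `norm_area`: `protrusion[q]` is the area of +1 pixels in
#' sector q divided by `norm_area`, `retraction[q]` the -1 area, and
#' `net[q] = protrusion[q] - retraction[q]` (positive = net extension).
#' Convention: the partition is computed from the earlier frame of the pair,
#' the reference state the change is measured against.
#'
#' @param diff a [difference_map()].
#' @param part a [partition_quadrants()] of the earlier frame.
#' @param norm_area normalization area in square micrometres (typically the
#'   mean spreading area of the frame pair).
#' @return list of class `quadrant_change` with named numeric vectors `net`,
#'   `protrusion`, `retraction` over the four quadrants, and `norm_area`.
#' @export
net_area_change <- function(diff, part, norm_area) {
  stopifnot(inherits(diff, "difference_map"), inherits(part, "quadrant_partition"))
  if (!identical(dim(diff$labels), dim(part$labels))) {
    stopf("input error: difference map and partition have different shapes")
  }
  if (!is_number(norm_area) || norm_area <= 0) {
    stopf("input error: norm_area must be > 0")
  }
  ps2 <- part$pixel_size^2
  prot <- retr <- stats::setNames(numeric(4), quadrant_levels)
  for (q in 1:4) {
    in_q <- part$labels == q
    prot[q] <- sum(diff$labels == 1L & in_q) * ps2 / norm_area
    retr[q] <- sum(diff$labels == -1L & in_q) * ps2 / norm_area
  }
  structure(list(net = prot - retr, protrusion = prot, retraction = retr,
                 norm_area = norm_area),
            class = "quadrant_change")
}

## Pick the unique frame at (cycle, phase) out of a stack, or NULL.
find_frame <- function(stack, cycle, phase) {
  hit <- Filter(function(f) f$cycle_index == cycle && f$phase_tag == phase, stack)
  if (length(hit) == 0) return(NULL)
  hit[[1]]
}

#' Per-cycle retraction/extension quadrant profiles at checkpoints
#'
#' For each checkpoint cycle, measures the retraction-phase quadrant change
#' (pre_stretch vs post_release pair: the immediate response to strain
#' release) and the extension-phase change (post_release vs relaxation_end
#' pair: protrusion during relaxation), pooling the two axial quadrants and
#' the two transverse quadrants (their mean), matching the familiar bar-plot
#' layout of per-cycle net extension/retraction.
#'
#' @param stack list of [cell_mask()] frames containing, for every requested
#'   checkpoint, the `pre_stretch`, `post_release` and `relaxation_end`
#'   frames of that cycle.
#' @param checkpoints integer vector of cycle indices to profile.
#' @param normalization `"pair_mean_area"` (default: mean spreading area of
#'   the two frames of each pair) or `"initial_area"` (area of the first
#'   frame in the stack).
#' @return long-format data.frame: `checkpoint`, `pair_type`
#'   (`"retraction"`/`"extension"`), `quadrant` (`"axial"`/`"transverse"`),
#'   `value` (signed area fraction).
#' @export
cycle_response_profile <- function(stack, checkpoints,
                                   normalization = c("pair_mean_area", "initial_area")) {
  normalization <- match.arg(normalization)
  if (length(stack) == 0) stopf("input error: empty frame stack")
  a0 <- spreading_area(stack[[1]])
  rows <- list()
  pool <- function(qc) c(axial = mean(qc$net[c("axial_plus", "axial_minus")]),
                         transverse = mean(qc$net[c("transverse_plus", "transverse_minus")]))
  for (cp in checkpoints) {
    pairs <- list(retraction = c("pre_stretch", "post_release"),
                  extension = c("post_release", "relaxation_end"))
    for (pt in names(pairs)) {
      f1 <- find_frame(stack, cp, pairs[[pt]][1])
      f2 <- find_frame(stack, cp, pairs[[pt]][2])
      if (is.null(f1) || is.null(f2)) {
        stopf("schedule error: checkpoint %d is missing its %s/%s frame pair",
              cp, pairs[[pt]][1], pairs[[pt]][2])
      }
      na <- if (normalization == "pair_mean_area") {
        (spreading_area(f1) + spreading_area(f2)) / 2
      } else a0
      qc <- net_area_change(difference_map(f1, f2), partition_quadrants(f1), na)
      pv <- pool(qc)
      rows[[length(rows) + 1]] <- data.frame(
        checkpoint = cp, pair_type = pt,
        quadrant = names(pv), value = unname(pv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
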