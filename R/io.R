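#' Write a mask frame stack as multi-page TIFF
#'
#' Masks are written as 8-bit grayscale pages (background 0, cell 255).
#' The acquisition schedule (time, cycle, phase per page) is written as a
#' sidecar CSV next to the TIFF so stacks can be round-tripped.
#'
#' @param frames list of [cell_mask()] frames with equal shape/calibration.
#' @param path output TIFF path; the schedule goes to `<path>.schedule.csv`.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(frames, path) {
  if (length(frames) == 0) stopf("input error: empty frame stack")
  pages <- lapply(frames, function(f) f$pixels * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  sched <- data.frame(
    page = seq_along(frames),
    time_s = vapply(frames, function(f) f$time, numeric(1)),
    cycle = vapply(frames, function(f) f$cycle_index, integer(1)),
    phase = vapply(frames, function(f) f$phase_tag, character(1)),
    pixel_size = vapply(frames, function(f) f$pixel_size, numeric(1)),
    stretch_axis = vapply(frames, function(f) f$stretch_axis, character(1)))
  utils::write.csv(sched, paste0(path, ".schedule.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a mask frame stack written by [write_mask_stack()]
#'
#' @param path TIFF path; pages binarized at 0.5. If the sidecar schedule
#'   CSV is missing, `pixel_size`, `stretch_axis` must be given and frames
#'   get page index as time.
#' @param pixel_size,stretch_axis calibration overrides when no sidecar
#'   schedule exists.
#' @return list of [cell_mask()] frames.
#' @export
read_mask_stack <- function(path, pixel_size = NULL, stretch_axis = "x") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sched_path <- paste0(path, ".schedule.csv")
  if (file.exists(sched_path)) {
    sched <- utils::read.csv(sched_path, stringsAsFactors = FALSE)
  } else {
    if (is.null(pixel_size)) {
      stopf("input error: no sidecar schedule; supply pixel_size")
    }
    sched <- data.frame(page = seq_along(pages), time_s = seq_along(pages),
                        cycle = 0L, phase = "pre_stretch",
                        pixel_size = pixel_size, stretch_axis = stretch_axis)
  }
  lapply(seq_along(pages), function(i) {
    cell_mask(pages[[i]] > 0.5, pixel_size = sched$pixel_size[i],
              time = sched$time_s[i], cycle_index = sched$cycle[i],
              phase_tag = sched$phase[i], stretch_axis = sched$stretch_axis[i])
  })
}

#' Write a micropattern image as 16-bit TIFF
#'
#' @param image a [micropattern_image()]; intensities are scaled to the
#'   16-bit range by their maximum.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_micropattern_tiff <- function(image, path) {
  stopifnot(inherits(image, "micropattern_image"))
  px <- image$pixels
  if (max(px) > 0) px <- px / max(px)
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a micropattern image from TIFF
#'
#' @param path TIFF path (first page used).
#' @param pixel_size um per pixel.
#' @return a [micropattern_image()] (grid_spec unknown, strain 0).
#' @export
read_micropattern_tiff <- function(path, pixel_size) {
  px <- tiff::readTIFF(path)
  if (is.list(px)) px <- px[[1]]
  if (length(dim(px)) == 3) px <- px[, , 1]
  micropattern_image(pmax(px, 0), pixel_size)
}

#' Read an experiment configuration from YAML
#'
#' The YAML mirrors [stretch_protocol()] + [dynamics_params()] /
#' [experiment_config()] fields under keys `protocol:`, `params:` (or
#' `condition:`) and top-level experiment keys. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return an [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("protocol", "params", "condition", "n_cells", "seed",
             "timepoints_min", "cell_radius", "irregularity", "pixel_size",
             "image_shape", "normalization", "probe_window_s", "output_dir")
  extra <- setdiff(names(y), known)
  if (length(extra)) stopf("configuration error: unknown config keys: %s",
                           paste(extra, collapse = ", "))
  protocol <- if (!is.null(y$protocol)) do.call(stretch_protocol, y$protocol) else
    stretch_protocol("square", 0.15, 0.5, n_cycles = 2700L)
  params <- if (!is.null(y$params)) do.call(dynamics_params, y$params) else
    y$condition %||% "control"
  args <- y[intersect(names(y), c("n_cells", "seed", "timepoints_min",
                                  "cell_radius", "irregularity", "pixel_size",
                                  "image_shape", "normalization",
                                  "probe_window_s", "output_dir"))]
  args$protocol <- protocol
  args$params <- params
  if (!is.null(args$timepoints_min)) args$timepoints_min <- as.numeric(args$timepoints_min)
  do.call(experiment_config, args)
}
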