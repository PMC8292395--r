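#' Configure a simulate-measure-tabulate experiment
#'
#' Desk-scale experiment configuration. The simulation runs in compressed
#' mode: the per-cycle rate laws are integrated in closed form over each
#' interval between consecutive checkpoints and applied as one effective
#' dynamics step per interval, so a multi-cell 90-minute run finishes in
#' seconds while preserving the laws' cumulative effect.
#'
#' @param protocol [stretch_protocol()] (its `sample_points` are ignored
#'   here; the pipeline schedules frames at `timepoints_min`).
#' @param params [dynamics_params()] or a preset condition name.
#' @param n_cells number of independent cells, `>= 1`.
#' @param seed root seed; per-cell streams are derived from it.
#' @param timepoints_min checkpoint times in minutes (must start at 0).
#' @param cell_radius initial cell radius, um.
#' @param irregularity initial-shape irregularity, see [make_initial_cell()].
#' @param pixel_size um per pixel.
#' @param image_shape frame dimensions c(rows, cols).
#' @param normalization quadrant-profile normalization, `"pair_mean_area"`
#'   or `"initial_area"`.
#' @param probe_window_s seconds of halted-cycling relaxation over which the
#'   per-checkpoint extension probes are measured (the slow persistent
#'   extension is integrated over 10 s for accuracy; actual per-cycle
#'   extension is the `relax_duration`/`probe_window_s` fraction of it).
#' @param output_dir directory for CSV/JSON outputs, or NULL to skip writing.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(protocol = stretch_protocol("square", 0.15, 0.5,
                                                          n_cycles = 2700L),
                              params = "control",
                              n_cells = 4L,
                              seed = 1L,
                              timepoints_min = c(0, 5, 15, 30, 45, 60, 90),
                              cell_radius = 50,
                              irregularity = 0.06,
                              pixel_size = 0.5,
                              image_shape = c(512L, 512L),
                              normalization = c("pair_mean_area", "initial_area"),
                              probe_window_s = 10,
                              output_dir = NULL) {
  if (is.character(params)) params <- preset_params(params)
  stopifnot(inherits(protocol, "stretch_protocol"),
            inherits(params, "dynamics_params"))
  if (!is_count(n_cells) || n_cells < 1) stopf("configuration error: n_cells must be >= 1")
  if (timepoints_min[1] != 0 || is.unsorted(timepoints_min, strictly = TRUE)) {
    stopf("configuration error: timepoints_min must start at 0 and increase")
  }
  normalization <- match.arg(normalization)
  structure(list(protocol = protocol, params = params,
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 timepoints_min = timepoints_min, cell_radius = cell_radius,
                 irregularity = irregularity, pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 normalization = normalization,
                 probe_window_s = probe_window_s, output_dir = output_dir),
            class = "experiment_config")
}

## Closed-form integrals of the rate laws over one checkpoint interval
## [t0, t1] minutes: total retraction fraction, relaxation seconds, and
## axial-protrusion fraction.
interval_laws <- function(protocol, params, t0_min, t1_min) {
  f <- protocol$frequency
  n0 <- floor(t0_min * 60 * f) + 1
  m <- round((t1_min - t0_min) * 60 * f)
  rd <- params$r_decay
  q <- exp(-1 / rd)
  transient <- (params$r0 - params$r_inf) *
    exp(-(n0 - 1) / rd) * (1 - q^m) / (1 - q)
  retract_frac <- params$r_inf * m + transient
  relax_s <- m * protocol$relax_duration
  tau <- params$p_A_tau
  s_per_min <- 60 * f * protocol$relax_duration
  prot_A_frac <- params$p_A0 * s_per_min * tau *
    (exp(-t0_min / tau) - exp(-t1_min / tau))
  list(retract_frac = retract_frac,
       prot_T_frac = params$p_T * relax_s,
       prot_A_frac = prot_A_frac,
       first_cycle = n0, n_cycles = m)
}

## Simulate one cell through the compressed checkpoint schedule.
## Returns list(frames = relaxed-state masks at each timepoint, probes).
simulate_cell_compressed <- function(config, cell_id) {
  pr <- config$protocol; pa <- config$params
  seed_i <- derive_seed(config$seed, cell_id)
  cur <- make_initial_cell(config$cell_radius, config$irregularity,
                           config$pixel_size, config$image_shape,
                           seed = seed_i)
  attr(cur, "noise_sigma") <- pa$noise_sigma
  tp <- config$timepoints_min
  frames <- vector("list", length(tp))
  cur$time <- 0; cur$cycle_index <- 0L; cur$phase_tag <- "pre_stretch"
  frames[[1]] <- strip_sim_attrs(cur)
  for (j in seq_len(length(tp) - 1)) {
    law <- interval_laws(pr, pa, tp[j], tp[j + 1])
    if (law$retract_frac > 0.9) {
      stopf("dynamics error: interval %d would retract %.0f%% of the cell",
            j, 100 * law$retract_frac)
    }
    res <- advance_mask(cur, law$retract_frac, law$prot_T_frac,
                        law$prot_A_frac, derive_seed(seed_i, j))
    cur <- res$mask
    cur$time <- tp[j + 1] * 60
    cur$cycle_index <- as.integer(law$first_cycle + law$n_cycles - 1)
    cur$phase_tag <- "relaxation_end"
    frames[[j + 1]] <- strip_sim_attrs(cur)
  }
  frames
}

strip_sim_attrs <- function(m) {
  attr(m, "noise_sigma") <- NULL
  attr(m, "cycle_log") <- NULL
  m
}

## Non-mutating per-checkpoint probe: from the given relaxed state, one
## release retraction at physical cycle n, then extension over window_s
## seconds of halted-cycling relaxation. Emits the three frames the
## quadrant profile needs.
probe_cycle <- function(state, params, protocol, n, cum_time_min, window_s, seed) {
  attr(state, "noise_sigma") <- params$noise_sigma
  t0 <- state$time
  pre <- state
  pre$cycle_index <- as.integer(n); pre$phase_tag <- "pre_stretch"
  res_r <- advance_mask(state, retraction_fraction(params, n), 0, 0,
                        derive_seed(seed, 1))
  post <- res_r$mask
  post$time <- t0 + protocol$stretch_duration
  post$cycle_index <- as.integer(n); post$phase_tag <- "post_release"
  res_p <- advance_mask(post, 0, params$p_T * window_s,
                        axial_rate(params, cum_time_min) * window_s,
                        derive_seed(seed, 2))
  relax <- res_p$mask
  relax$time <- t0 + protocol$stretch_duration + window_s
  relax$cycle_index <- as.integer(n); relax$phase_tag <- "relaxation_end"
  lapply(list(pre, post, relax), strip_sim_attrs)
}

#' Run a full simulate-measure-tabulate experiment
#'
#' Simulates `n_cells` independent cells under the configured protocol and
#' dynamics (per-cell derived seeds), measures the relaxed-state shape time
#' course of every cell, profiles per-cycle quadrant retraction/extension at
#' the checkpoints (physical cycles 1 and 2, then each later checkpoint,
#' probed over `probe_window_s` seconds of halted cycling), and assembles
#' population means with SEM. If `output_dir` is set, writes
#' `shape_timecourse.csv`, `population_means.csv`, `quadrant_profile.csv`
#' and a `manifest.json` (config echo, package version, seed); outputs are
#' bitwise-reproducible for a fixed config.
#'
#' @param config an [experiment_config()].
#' @return list of class `result_bundle`: `shape_timecourse` (per-cell
#'   rows), `population_means`, `quadrant_profile`, `condition`, `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  pr <- config$protocol; pa <- config$params
  tp <- config$timepoints_min
  shape_rows <- list(); profile_rows <- list()
  for (i in seq_len(config$n_cells)) {
    frames <- simulate_cell_compressed(config, i)
    st <- summarize_timecourse(frames)
    st <- cbind(cell_id = i, st, time_min = st$time / 60)
    shape_rows[[i]] <- st

    seed_i <- derive_seed(config$seed, i)
    probe_stack <- list(); cps <- integer(0)
    add_probe <- function(state, n, cum_min, k) {
      probe_stack <<- c(probe_stack,
                        probe_cycle(state, pa, pr, n, cum_min,
                                    config$probe_window_s,
                                    derive_seed(seed_i, 900, k)))
      cps <<- c(cps, n)
    }
    ## cycles 1 and 2 from the initial state (cycle 1 advances a copy)
    st0 <- frames[[1]]
    add_probe(st0, 1L, 0, 1L)
    attr(st0, "noise_sigma") <- pa$noise_sigma
    c1 <- advance_mask(st0, retraction_fraction(pa, 1),
                       pa$p_T * pr$relax_duration,
                       axial_rate(pa, 0) * pr$relax_duration,
                       derive_seed(seed_i, 901))$mask
    c1$time <- pr$period
    add_probe(strip_sim_attrs(c1), 2L, pr$period / 60, 2L)
    for (j in seq(2, length(tp))) {
      n <- floor(tp[j] * 60 * pr$frequency) + 1L
      add_probe(frames[[j]], n, tp[j], 2L + j)
    }
    qp <- cycle_response_profile(probe_stack, cps,
                                 normalization = config$normalization)
    qp <- cbind(cell_id = i, qp,
                checkpoint_min = qp$checkpoint / (60 * pr$frequency))
    profile_rows[[i]] <- qp
  }
  shape <- do.call(rbind, shape_rows)
  profile <- do.call(rbind, profile_rows)
  pop <- population_means(shape)
  bundle <- structure(list(shape_timecourse = shape,
                           population_means = pop,
                           quadrant_profile = profile,
                           condition = pa$condition,
                           config = config),
                      class = "result_bundle")
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  bundle
}

## Per-timepoint mean and SEM (sd/sqrt(n)) over cells.
population_means <- function(shape) {
  metrics <- c("orientation_index", "axial_length", "transverse_length", "area")
  out <- lapply(split(shape, shape$time_min), function(d) {
    n <- nrow(d)
    row <- data.frame(time_min = d$time_min[1], n = n)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sem")]] <- stats::sd(d[[m]]) / sqrt(n)
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$time_min), , drop = FALSE]
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("I/O error: cannot create output directory '%s'", dir)
  }
  utils::write.csv(bundle$shape_timecourse,
                   file.path(dir, "shape_timecourse.csv"), row.names = FALSE)
  utils::write.csv(bundle$population_means,
                   file.path(dir, "population_means.csv"), row.names = FALSE)
  utils::write.csv(bundle$quadrant_profile,
                   file.path(dir, "quadrant_profile.csv"), row.names = FALSE)
  cfg <- bundle$config
  manifest <- list(
    package = "cyclostretch",
    version = as.character(utils::packageVersion("cyclostretch")),
    seed = cfg$seed, n_cells = cfg$n_cells, condition = bundle$condition,
    timepoints_min = cfg$timepoints_min,
    protocol = cfg$protocol[c("waveform", "amplitude", "frequency",
                              "stretch_duration", "relax_duration",
                              "transverse_ratio", "transverse_sign")],
    params = unclass(cfg$params),
    cell_radius = cfg$cell_radius, irregularity = cfg$irregularity,
    pixel_size = cfg$pixel_size, image_shape = cfg$image_shape,
    normalization = cfg$normalization, probe_window_s = cfg$probe_window_s)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}

#' Compare population readouts across conditions
#'
#' Merges the per-timepoint population means of two or more experiments
#' (sharing protocol and timepoints) into one long table keyed by timepoint
#' and condition, for side-by-side condition comparisons.
#'
#' @param bundles list of `result_bundle` objects (from [run_experiment()])
#'   or of [experiment_config()]s (which are run first).
#' @return data.frame: `condition` column plus the population-mean columns.
#' @export
compare_conditions <- function(bundles) {
  if (length(bundles) < 2) stopf("input error: need >= 2 conditions")
  bundles <- lapply(bundles, function(b) {
    if (inherits(b, "experiment_config")) run_experiment(b) else b
  })
  tps <- lapply(bundles, function(b) b$population_means$time_min)
  for (k in seq(2, length(tps))) {
    if (!isTRUE(all.equal(tps[[1]], tps[[k]]))) {
      stopf("alignment error: condition %d has mismatched timepoints", k)
    }
  }
  out <- do.call(rbind, lapply(bundles, function(b) {
    cbind(condition = b$condition, b$population_means)
  }))
  rownames(out) <- NULL
  out
}

#' Short-window fraction of the relaxation-phase extension
#'
#' Extension during the ~1 s relaxation phase of a cycle is slow, so it is
#' measured over a longer halted-cycling window for accuracy; this utility
#' returns the percentage of the long-window integral accrued in the short
#' window. For the constant-rate protrusion law the ratio is
#' `100 * short/long` (10\% for 1 s vs 10 s); with a within-relaxation
#' exponential decay of time constant `tau` it is
#' `100 * (1 - exp(-t1/tau)) / (1 - exp(-t2/tau))`.
#'
#' @param rate protrusion rate (area fraction per second), `>= 0`.
#' @param short_window,long_window window lengths in seconds, `> 0`.
#' @param tau optional within-relaxation decay time constant in seconds
#'   (`Inf` = constant rate).
#' @return percentage (0-100 scale).
#' @export
relaxation_fraction_check <- function(rate, short_window, long_window, tau = Inf) {
  if (short_window <= 0 || long_window <= 0) stopf("input error: windows must be > 0")
  if (rate < 0) stopf("input error: rate must be >= 0")
  long_int <- if (is.finite(tau)) rate * tau * (1 - exp(-long_window / tau)) else
    rate * long_window
  if (long_int == 0) stopf("undefined-ratio error: zero long-window integral")
  short_int <- if (is.finite(tau)) rate * tau * (1 - exp(-short_window / tau)) else
    rate * short_window
  100 * short_int / long_int
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("result_bundle [%s]: %d cells, %d timepoints\n",
              x$condition, x$config$n_cells, length(x$config$timepoints_min)))
  print(x$population_means[, c("time_min", "orientation_index_mean",
                               "axial_length_mean", "transverse_length_mean",
                               "area_mean")])
  invisible(x)
}
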