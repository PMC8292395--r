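#' Define a cyclic-stretch protocol
#'
#' A `stretch_protocol` describes the uniaxial strain waveform applied to the
#' elastic substrate and the acquisition schedule that aligns image frames to
#' phases of the stretch cycle. One cycle consists of a stretch window of
#' `stretch_duration` seconds followed by a relaxation window of
#' `relax_duration` seconds; for a periodic protocol the two must sum to
#' `1/frequency`.
#'
#' Phase tags used by the scheduler:
#' \describe{
#'   \item{`pre_stretch`}{relaxed state at the start of a cycle.}
#'   \item{`during_stretch`}{on the stretched substrate, mid stretch window.}
#'   \item{`post_release`}{immediately after strain release (cells have
#'     undergone the immediate retraction, no protrusion yet).}
#'   \item{`relaxation_end`}{end of the relaxation window of the cycle.}
#' }
#'
#' @param waveform one of `"square"`, `"triangular"`, `"trapezoid"`.
#' @param amplitude peak axial engineering strain, in (0, 0.20]. The substrate
#'   model is validated for strains up to 20\%.
#' @param frequency cycle frequency in Hz.
#' @param n_cycles number of stretch cycles.
#' @param stretch_duration seconds of the stretch window per cycle (time at
#'   peak strain for square/trapezoid).
#' @param relax_duration seconds of the relaxation window per cycle.
#' @param transverse_ratio |transverse|/|axial| substrate strain magnitude
#'   ratio; the default 0.15 reflects a predominantly uniaxial substrate
#'   (transverse strain below 16\% of axial).
#' @param transverse_sign sign of the transverse substrate strain relative to
#'   axial; `-1` (default) models Poisson-like lateral contraction.
#' @param ramp_time seconds of the up/down ramp used by the trapezoid
#'   waveform; ignored otherwise.
#' @param sample_points data.frame with columns `cycle` and `phase` naming
#'   the frames to emit; `NULL` means none (callers may supply later).
#'
#' @return an object of class `stretch_protocol`.
#' @seealso [waveform_strain()], [simulate_timecourse()]
#' @export
#' @examples
#' p <- stretch_protocol("square", amplitude = 0.15, frequency = 0.5, n_cycles = 10)
#' waveform_strain(p, c(0, 0.5, 1.5))
stretch_protocol <- function(waveform = c("square", "triangular", "trapezoid"),
                             amplitude = 0.15,
                             frequency = 0.5,
                             n_cycles = 1L,
                             stretch_duration = NULL,
                             relax_duration = NULL,
                             transverse_ratio = 0.15,
                             transverse_sign = -1,
                             ramp_time = NULL,
                             sample_points = NULL) {
  waveform <- match.arg(waveform)
  if (!is_number(amplitude) || amplitude <= 0 || amplitude > 0.20) {
    stopf("configuration error: amplitude must lie in (0, 0.20], got %s", amplitude)
  }
  if (!is_number(frequency) || frequency <= 0) {
    stopf("configuration error: frequency must be > 0")
  }
  period <- 1 / frequency
  if (is.null(stretch_duration) && is.null(relax_duration)) {
    stretch_duration <- period / 2
    relax_duration <- period / 2
  } else if (is.null(relax_duration)) {
    relax_duration <- period - stretch_duration
  } else if (is.null(stretch_duration)) {
    stretch_duration <- period - relax_duration
  }
  if (stretch_duration <= 0 || relax_duration <= 0 ||
      abs(stretch_duration + relax_duration - period) > 1e-9) {
    stopf("configuration error: stretch_duration + relax_duration must equal 1/frequency")
  }
  if (!is_number(transverse_ratio) || transverse_ratio < 0 || transverse_ratio > 0.16) {
    stopf("configuration error: transverse_ratio must lie in [0, 0.16]")
  }
  if (!transverse_sign %in% c(-1, 1)) {
    stopf("configuration error: transverse_sign must be -1 or +1")
  }
  if (!is_count(n_cycles) || n_cycles < 1) {
    stopf("configuration error: n_cycles must be a positive count")
  }
  ramp_time <- ramp_time %||% (period / 10)
  if (waveform == "trapezoid" &&
      (ramp_time <= 0 || ramp_time > min(stretch_duration, relax_duration))) {
    stopf("configuration error: trapezoid ramp_time must lie in (0, min(stretch, relax)]")
  }
  if (!is.null(sample_points)) {
    sample_points <- validate_sample_points(sample_points, n_cycles)
  }
  structure(
    list(waveform = waveform, amplitude = amplitude, frequency = frequency,
         period = period, n_cycles = as.integer(n_cycles),
         stretch_duration = stretch_duration, relax_duration = relax_duration,
         transverse_ratio = transverse_ratio, transverse_sign = transverse_sign,
         ramp_time = ramp_time, sample_points = sample_points),
    class = "stretch_protocol")
}

phase_tags <- c("pre_stretch", "during_stretch", "post_release", "relaxation_end")

validate_sample_points <- function(sp, n_cycles) {
  sp <- as.data.frame(sp)
  if (!all(c("cycle", "phase") %in% names(sp))) {
    stopf("configuration error: sample_points needs columns 'cycle' and 'phase'")
  }
  if (any(!sp$phase %in% phase_tags)) {
    stopf("configuration error: unknown phase tag(s): %s",
          paste(setdiff(unique(sp$phase), phase_tags), collapse = ", "))
  }
  if (any(sp$cycle < 1) || any(sp$cycle > n_cycles) || any(sp$cycle != round(sp$cycle))) {
    stopf("configuration error: sample_points reference cycles outside 1..%d", n_cycles)
  }
  sp$cycle <- as.integer(sp$cycle)
  sp$phase <- as.character(sp$phase)
  sp[order(sp$cycle, match(sp$phase, phase_tags)), c("cycle", "phase"), drop = FALSE]
}

#' Evaluate the substrate strain waveform
#'
#' Returns the axial engineering strain at times `t` (seconds from protocol
#' start), periodic with period `1/frequency`. The square waveform holds the
#' amplitude throughout the stretch window and is zero during relaxation; the
#' triangular waveform ramps linearly up to the amplitude at the midpoint of
#' the stretch window and back to zero at its end (no dwell at amplitude); the
#' trapezoid ramps over `ramp_time`, dwells at amplitude for the remainder of
#' the stretch window, ramps down, and dwells at zero. All waveforms evaluate
#' to zero at the start of each cycle.
#'
#' @param protocol a [stretch_protocol()].
#' @param t numeric vector of times in seconds, all `>= 0`.
#' @return numeric vector of axial strains in `[0, amplitude]`.
#' @export
waveform_strain <- function(protocol, t) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  if (any(t < 0)) stopf("t must be >= 0")
  tp <- t %% protocol$period
  a <- protocol$amplitude
  sd <- protocol$stretch_duration
  switch(protocol$waveform,
    square = ifelse(tp > 0 & tp <= sd, a, 0),
    triangular = {
      half <- sd / 2
      up <- tp > 0 & tp <= half
      down <- tp > half & tp < sd
      out <- numeric(length(tp))
      out[up] <- a * tp[up] / half
      out[down] <- a * (sd - tp[down]) / half
      out
    },
    trapezoid = {
      r <- protocol$ramp_time
      out <- numeric(length(tp))
      up <- tp > 0 & tp <= r
      dwell <- tp > r & tp <= sd
      down <- tp > sd & tp < sd + r
      out[up] <- a * tp[up] / r
      out[dwell] <- a
      out[down] <- a * (sd + r - tp[down]) / r
      out
    },
    stopf("configuration error: unknown waveform '%s'", protocol$waveform))
}

#' Build a phase-checkpoint acquisition schedule
#'
#' Convenience constructor for `sample_points`: emits the requested phase
#' tags at each listed cycle.
#'
#' @param cycles integer vector of cycle indices.
#' @param phases character vector of phase tags emitted at every listed cycle.
#' @return data.frame with columns `cycle`, `phase`.
#' @export
schedule_at_cycles <- function(cycles, phases = phase_tags) {
  expand.grid(phase = phases, cycle = cycles,
              stringsAsFactors = FALSE)[, c("cycle", "phase")]
}

#' @export
print.stretch_protocol <- function(x, ...) {
  cat(sprintf("stretch_protocol: %s, amplitude %.3f, %.3g Hz, %d cycles\n",
              x$waveform, x$amplitude, x$frequency, x$n_cycles))
  cat(sprintf("  stretch %.3g s + relax %.3g s; transverse ratio %.3f (sign %+d)\n",
              x$stretch_duration, x$relax_duration, x$transverse_ratio,
              x$transverse_sign))
  if (!is.null(x$sample_points)) {
    cat(sprintf("  %d scheduled frames\n", nrow(x$sample_points)))
  }
  invisible(x)
}
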