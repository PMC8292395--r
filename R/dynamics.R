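#' Per-cycle retraction/protrusion rate-law parameters
#'
#' Parameters of the per-cycle cell-response model: on each release of
#' stretching the cell immediately retracts a fraction of its spreading area
#' uniformly around the perimeter, with magnitude
#' `r(n) = r_inf + (r0 - r_inf) * exp(-(n - 1)/r_decay)` at cycle `n` — a
#' strong first-cycle response decaying rapidly towards a small persistent
#' floor `r_inf`. During the relaxation window the cell extends: area is
#' added in the two transverse quadrants at the constant rate `p_T`
#' (fraction of spreading area per second of relaxation) and in the two
#' axial quadrants at the decaying rate
#' `p_A(t) = p_A0 * exp(-t/p_A_tau)`, with `t` the cumulative stretching
#' time in minutes. Setting `r_inf = 0` recovers a pure exponential
#' retraction decay.
#'
#' @param r0 retraction area fraction at the first release, `>= 0`.
#' @param r_decay per-cycle decay constant of the retraction transient,
#'   `> 0` (cycles).
#' @param r_inf persistent per-cycle retraction floor, `>= 0` (fraction of
#'   area per cycle).
#' @param p_T transverse protrusion rate (area fraction per second of
#'   relaxation), constant over cycles, `>= 0`.
#' @param p_A0 initial axial protrusion rate (area fraction per second),
#'   `>= 0`.
#' @param p_A_tau decay time of the axial rate, `> 0` (minutes of cumulative
#'   stretching).
#' @param noise_sigma boundary roughness amplitude in micrometres.
#' @param condition condition label, one of `"control"`, `"blebbistatin"`,
#'   `"nocodazole"`, `"nocodazole_blebbistatin"`, or `"custom"`.
#' @return object of class `dynamics_params`.
#' @seealso [preset_params()] for the documented condition presets.
#' @export
dynamics_params <- function(r0 = 0, r_decay = 1, r_inf = 0, p_T = 0,
                            p_A0 = 0, p_A_tau = 1, noise_sigma = 0,
                            condition = "custom") {
  if (r0 < 0 || p_T < 0 || p_A0 < 0 || r_inf < 0) {
    stopf("configuration error: r0, r_inf, p_T, p_A0 must be >= 0")
  }
  if (r_decay <= 0 || p_A_tau <= 0) {
    stopf("configuration error: r_decay and p_A_tau must be > 0")
  }
  if (noise_sigma < 0) stopf("configuration error: noise_sigma must be >= 0")
  structure(list(r0 = r0, r_decay = r_decay, r_inf = r_inf, p_T = p_T,
                 p_A0 = p_A0, p_A_tau = p_A_tau, noise_sigma = noise_sigma,
                 condition = condition),
            class = "dynamics_params")
}

#' Retraction fraction at cycle n
#'
#' Evaluates the per-cycle retraction law
#' `r(n) = r_inf + (r0 - r_inf) * exp(-(n - 1)/r_decay)`.
#'
#' @param params a [dynamics_params()].
#' @param n cycle index (vectorized), `>= 1`.
#' @return area fraction removed at release of cycle `n`.
#' @export
retraction_fraction <- function(params, n) {
  stopifnot(inherits(params, "dynamics_params"))
  if (any(n < 1)) stopf("cycle index must be >= 1")
  params$r_inf + (params$r0 - params$r_inf) * exp(-(n - 1) / params$r_decay)
}

#' Axial protrusion rate at cumulative stretching time t
#'
#' Evaluates `p_A(t) = p_A0 * exp(-t/p_A_tau)` with `t` in minutes.
#'
#' @param params a [dynamics_params()].
#' @param t_min cumulative stretching time in minutes (vectorized).
#' @return area fraction per second of relaxation.
#' @export
axial_rate <- function(params, t_min) {
  stopifnot(inherits(params, "dynamics_params"))
  params$p_A0 * exp(-t_min / params$p_A_tau)
}

#' Documented drug-condition parameter presets
#'
#' Default rate-law parameter sets for the four experimental conditions.
#' The paperless constants are model choices calibrated to reproduce the
#' qualitative control phenotype (transverse reorientation with early axial
#' shortening and late transverse elongation) and the drug-condition
#' orderings: relative to control, the myosin II inhibitor preset
#' (`blebbistatin`) suppresses retraction and transverse protrusion while
#' sustaining axial protrusion, so cells drift towards axial alignment; the
#' microtubule-disassembly preset (`nocodazole`) enhances both retraction
#' and transverse protrusion, amplifying transverse reorientation; the
#' combined preset amplifies the blebbistatin pattern.
#'
#' @param condition one of `"control"`, `"blebbistatin"`, `"nocodazole"`,
#'   `"nocodazole_blebbistatin"`.
#' @return a [dynamics_params()].
#' @export
preset_params <- function(condition = c("control", "blebbistatin",
                                        "nocodazole", "nocodazole_blebbistatin")) {
  if (length(condition) == 1 && !condition %in%
        c("control", "blebbistatin", "nocodazole", "nocodazole_blebbistatin")) {
    stopf("configuration error: unknown condition '%s'", condition)
  }
  condition <- match.arg(condition)
  switch(condition,
    control = dynamics_params(
      r0 = 0.05, r_decay = 3, r_inf = 1.1e-4,
      p_T = 2.4e-4, p_A0 = 0.8e-4, p_A_tau = 10,
      noise_sigma = 0.3, condition = condition),
    blebbistatin = dynamics_params(
      r0 = 0.002, r_decay = 3, r_inf = 0,
      p_T = 1e-5, p_A0 = 1.0e-4, p_A_tau = 900,
      noise_sigma = 0.3, condition = condition),
    nocodazole = dynamics_params(
      r0 = 0.08, r_decay = 3, r_inf = 1.4e-4,
      p_T = 3.2e-4, p_A0 = 0.8e-4, p_A_tau = 6,
      noise_sigma = 0.3, condition = condition),
    nocodazole_blebbistatin = dynamics_params(
      r0 = 0.001, r_decay = 3, r_inf = 0,
      p_T = 0, p_A0 = 1.4e-4, p_A_tau = 900,
      noise_sigma = 0.3, condition = condition))
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf(
    "dynamics_params [%s]: r0=%.3g r_decay=%.3g r_inf=%.3g p_T=%.3g/s p_A0=%.3g/s p_A_tau=%.3g min noise=%.3g um\n",
    x$condition, x$r0, x$r_decay, x$r_inf, x$p_T, x$p_A0, x$p_A_tau,
    x$noise_sigma))
  invisible(x)
}
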