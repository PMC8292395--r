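## Mask-evolution workers for the per-cycle retraction/protrusion model.

## Remove exactly k foreground pixels, innermost-boundary first (increasing
## distance-to-background, ties broken by linear index). Fragments detached
## by the removal are also removed and counted. Returns list(px, removed).
retract_mask <- function(px, k) {
  if (k <= 0) return(list(px = px, removed = 0L))
  n_fg <- sum(px)
  if (k >= n_fg) {
    stopf("dynamics error: retraction would empty the mask (removing %d of %d px)",
          k, n_fg)
  }
  d <- EBImage::distmap(px * 1)
  fg <- which(px)
  ord <- fg[order(d[fg], fg)]
  px[ord[seq_len(k)]] <- FALSE
  lab <- EBImage::bwlabel(px * 1)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    keep <- which.max(sizes)
    px <- lab == keep
  }
  list(px = px, removed = n_fg - sum(px))
}

## Background pixels 4-adjacent to the mask (the growth ring), excluding the
## 1-pixel image border so masks never touch it.
growth_ring <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  adj <- matrix(FALSE, nr, nc)
  adj[-1, ] <- adj[-1, ] | px[-nr, ]
  adj[-nr, ] <- adj[-nr, ] | px[-1, ]
  adj[, -1] <- adj[, -1] | px[, -nc]
  adj[, -nc] <- adj[, -nc] | px[, -1]
  adj <- adj & !px
  adj[1, ] <- FALSE; adj[nr, ] <- FALSE; adj[, 1] <- FALSE; adj[, nc] <- FALSE
  adj
}

## Grow the mask by exactly k pixels inside one angular sector, ring by ring
## (which preserves 4-connectivity). `axis_angle` is the sector's outward
## direction in radians in (u, v) coordinates; partial rings are filled in
## order of noise-perturbed angular proximity to that axis, which
## concentrates growth at the sector tip and roughens the boundary.
protrude_sector <- function(px, k, sector, du, dv, axis_angle, noise_sd_rad) {
  if (k <= 0) return(list(px = px, added = 0L))
  added <- 0L
  while (added < k) {
    ring <- which(growth_ring(px) & sector)
    if (length(ring) == 0) {
      stopf("dynamics error: no room to protrude (frame too small for the requested growth)")
    }
    need <- k - added
    if (length(ring) <= need) {
      px[ring] <- TRUE
      added <- added + length(ring)
    } else {
      ang <- atan2(dv[ring], du[ring]) - axis_angle
      ang <- abs(atan2(sin(ang), cos(ang)))   # wrapped angular distance
      if (noise_sd_rad > 0) ang <- ang + stats::rnorm(length(ring), 0, noise_sd_rad)
      px[ring[order(ang, ring)[seq_len(need)]]] <- TRUE
      added <- k
    }
  }
  list(px = px, added = added)
}

## One model step: uniform-perimeter retraction of `retract_frac` of the
## current area, then protrusion adding `prot_T_frac` of the post-retraction
## area split between the transverse sectors and `prot_A_frac` between the
## axial sectors. Fractions are converted to exact pixel counts, so logged
## areas satisfy exact mass bookkeeping. Returns list(mask, log).
advance_mask <- function(mask, retract_frac, prot_T_frac, prot_A_frac, seed) {
  px <- mask$pixels
  ps <- mask$pixel_size
  a_px <- sum(px)
  k_r <- round(retract_frac * a_px)
  res <- retract_mask(px, k_r)
  px <- res$px
  removed <- res$removed

  a_px <- sum(px)
  k_T <- round(prot_T_frac * a_px)
  k_A <- round(prot_A_frac * a_px)
  added <- c(axial_plus = 0L, axial_minus = 0L,
             transverse_plus = 0L, transverse_minus = 0L)
  if (k_T > 0 || k_A > 0) {
    idx <- which(px, arr.ind = TRUE)
    cx <- mean((idx[, 2] - 0.5) * ps); cy <- mean((idx[, 1] - 0.5) * ps)
    co <- pixel_coords_um(nrow(px), ncol(px), ps)
    if (mask$stretch_axis == "x") {
      du <- co$x - cx; dv <- co$y - cy
    } else {
      du <- co$y - cy; dv <- co$x - cx
    }
    sectors <- list(
      axial_plus = du >= abs(dv) & du > 0,
      axial_minus = -du >= abs(dv) & du < 0,
      transverse_plus = dv > abs(du),
      transverse_minus = dv < -abs(du))
    axes <- c(axial_plus = 0, axial_minus = pi,
              transverse_plus = pi / 2, transverse_minus = -pi / 2)
    r_mean <- sqrt(a_px / pi) * ps
    noise_sd_rad <- mask_noise_sd_rad(attr(mask, "noise_sigma"), r_mean)
    quotas <- c(axial_plus = ceiling(k_A / 2), axial_minus = floor(k_A / 2),
                transverse_plus = ceiling(k_T / 2), transverse_minus = floor(k_T / 2))
    with_seed(seed, {
      for (q in names(quotas)) {
        if (quotas[[q]] > 0) {
          res <- protrude_sector(px, quotas[[q]], sectors[[q]], du, dv,
                                 axes[[q]], noise_sd_rad)
          px <- res$px
          added[q] <- res$added
        }
      }
    })
  }
  mask$pixels <- px
  list(mask = mask,
       log = list(
         retraction_area_um2 = removed * ps^2,
         protrusion_T_um2 = sum(added[c("transverse_plus", "transverse_minus")]) * ps^2,
         protrusion_A_um2 = sum(added[c("axial_plus", "axial_minus")]) * ps^2,
         protrusion_by_quadrant_um2 = added * ps^2))
}

mask_noise_sd_rad <- function(noise_sigma, r_mean) {
  if (is.null(noise_sigma) || noise_sigma <= 0 || r_mean <= 0) return(0)
  noise_sigma / r_mean
}

#' Advance a cell mask through one stretch cycle
#'
#' Applies the per-cycle response model to a relaxed-state mask: (1) the
#' immediate uniform perimeter retraction on strain release, removing the
#' area fraction given by [retraction_fraction()] at this cycle equally
#' around the boundary, then (2) protrusion during `relax_time` seconds of
#' relaxation, adding area at the constant transverse rate `p_T` (split
#' between the two transverse quadrants) and the decaying axial rate
#' [axial_rate()] at `cum_time_min` (split between the two axial quadrants),
#' realized as sector-restricted boundary dilation. The single-component
#' mask invariant is preserved.
#'
#' @param cell relaxed-state [cell_mask()].
#' @param params [dynamics_params()].
#' @param cycle_index cycle number, `>= 1`.
#' @param relax_time seconds of relaxation available for protrusion.
#' @param cum_time_min cumulative stretching time in minutes at this cycle
#'   (drives the axial-rate decay).
#' @param seed integer seed for the boundary-roughness noise.
#' @return the relaxed-state [cell_mask()] after the cycle, with the area
#'   bookkeeping attached as attribute `"cycle_log"` (retraction and
#'   per-quadrant protrusion areas in um^2).
#' @export
step_cycle <- function(cell, params, cycle_index, relax_time,
                       cum_time_min = 0, seed = 1L) {
  stopifnot(inherits(cell, "cell_mask"), inherits(params, "dynamics_params"))
  if (relax_time < 0) stopf("relax_time must be >= 0")
  if (cycle_index < 1) stopf("cycle_index must be >= 1")
  attr(cell, "noise_sigma") <- params$noise_sigma
  rf <- retraction_fraction(params, cycle_index)
  res <- advance_mask(cell, rf,
                      params$p_T * relax_time,
                      axial_rate(params, cum_time_min) * relax_time,
                      seed)
  out <- res$mask
  attr(out, "noise_sigma") <- NULL
  out$cycle_index <- as.integer(cycle_index)
  out$phase_tag <- "relaxation_end"
  attr(out, "cycle_log") <- res$log
  out
}

#' Simulate a cell-shape time course under a stretch protocol
#'
#' Runs the per-cycle retraction/protrusion model for every cycle of the
#' protocol, emitting frames at the scheduled (cycle, phase) sample points
#' and logging ground truth. `during_stretch` frames are the current mask
#' with the substrate affine map applied (amplitude axial strain, and
#' `transverse_sign * transverse_ratio * amplitude` transverse): cells
#' passively follow the substrate during the stretch window and show no
#' active dynamics there. `post_release` frames capture the state right
#' after the immediate retraction; `relaxation_end` frames the state after
#' protrusion over the relaxation window. Fully reproducible from `seed`.
#'
#' @param protocol [stretch_protocol()] whose `sample_points` name the
#'   frames to emit.
#' @param params [dynamics_params()].
#' @param cell0 initial relaxed [cell_mask()].
#' @param seed root seed; per-cycle streams are derived from it.
#' @return list with `frames` (list of [cell_mask()]) and `ground_truth`
#'   (data.frame: `cycle`, `time_s`, `retraction_area_um2`,
#'   `protrusion_T_um2`, `protrusion_A_um2`, `area_um2`).
#' @export
simulate_timecourse <- function(protocol, params, cell0, seed = 1L) {
  stopifnot(inherits(protocol, "stretch_protocol"),
            inherits(params, "dynamics_params"),
            inherits(cell0, "cell_mask"))
  sp <- protocol$sample_points
  if (is.null(sp)) {
    stopf("configuration error: protocol has no sample_points schedule")
  }
  eps_ax <- protocol$amplitude
  eps_tr <- protocol$transverse_sign * protocol$transverse_ratio * eps_ax
  period <- protocol$period
  wants <- function(cyc, ph) any(sp$cycle == cyc & sp$phase == ph)
  frames <- list()
  gt <- list()
  cur <- cell0
  attr(cur, "noise_sigma") <- params$noise_sigma
  emit <- function(m, t, cyc, ph) {
    m$time <- t; m$cycle_index <- as.integer(cyc); m$phase_tag <- ph
    attr(m, "noise_sigma") <- NULL
    attr(m, "cycle_log") <- NULL
    frames[[length(frames) + 1]] <<- m
  }
  last_cycle <- max(sp$cycle)
  for (n in seq_len(last_cycle)) {
    t_n <- (n - 1) * period
    if (wants(n, "pre_stretch")) emit(cur, t_n, n, "pre_stretch")
    if (wants(n, "during_stretch")) {
      emit(apply_substrate_strain(cur, eps_ax, eps_tr),
           t_n + protocol$stretch_duration / 2, n, "during_stretch")
    }
    rf <- retraction_fraction(params, n)
    res_r <- advance_mask(cur, rf, 0, 0, derive_seed(seed, n, 1))
    cur <- res_r$mask
    if (wants(n, "post_release")) {
      emit(cur, t_n + protocol$stretch_duration, n, "post_release")
    }
    cum_min <- (n - 1) * period / 60
    res_p <- advance_mask(cur, 0,
                          params$p_T * protocol$relax_duration,
                          axial_rate(params, cum_min) * protocol$relax_duration,
                          derive_seed(seed, n, 2))
    cur <- res_p$mask
    if (wants(n, "relaxation_end")) emit(cur, t_n + period, n, "relaxation_end")
    gt[[n]] <- data.frame(
      cycle = n, time_s = t_n + protocol$stretch_duration,
      retraction_area_um2 = res_r$log$retraction_area_um2,
      protrusion_T_um2 = res_p$log$protrusion_T_um2,
      protrusion_A_um2 = res_p$log$protrusion_A_um2,
      area_um2 = sum(cur$pixels) * cur$pixel_size^2)
  }
  list(frames = frames, ground_truth = do.call(rbind, gt))
}
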