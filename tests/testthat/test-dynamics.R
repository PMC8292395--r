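test_that("null dynamics leave the mask unchanged", {
  m <- make_disc(15, 1, c(64L, 64L))
  out <- step_cycle(m, dynamics_params(), 1, relax_time = 10)
  expect_identical(out$pixels, m$pixels)
  lg <- attr(out, "cycle_log")
  expect_equal(lg$retraction_area_um2, 0)
  expect_equal(lg$protrusion_T_um2 + lg$protrusion_A_um2, 0)
})

test_that("retraction removes the prescribed area fraction uniformly", {
  m <- make_disc()  # r = 25 um, 0.5 um/px
  p <- dynamics_params(r0 = 0.1, r_decay = 3)
  out <- step_cycle(m, p, 1, relax_time = 0)
  a0 <- spreading_area(m)
  expect_lt(abs((a0 - spreading_area(out)) / a0 - 0.1), 0.005)
  # removal is spread over all quadrants roughly equally
  part <- partition_quadrants(m)
  m$time <- 0; out$time <- 1
  qc <- net_area_change(difference_map(m, out), part, a0)
  expect_true(all(qc$net < 0))
  expect_lt(diff(range(qc$net)) / abs(mean(qc$net)), 0.10)
})

test_that("per-cycle retraction follows the exponential-decay law", {
  p <- dynamics_params(r0 = 0.05, r_decay = 3)
  expect_equal(retraction_fraction(p, 2) / retraction_fraction(p, 1), exp(-1 / 3))
  # measured removed areas across two cycles match the law within 10%
  m <- make_disc()
  s1 <- step_cycle(m, p, 1, relax_time = 0)
  s2 <- step_cycle(s1, p, 2, relax_time = 0)
  r1 <- attr(s1, "cycle_log")$retraction_area_um2
  r2 <- attr(s2, "cycle_log")$retraction_area_um2
  expect_lt(abs(r2 / r1 / exp(-1 / 3) - 1), 0.10)
  # the persistent floor lifts the law
  pf <- dynamics_params(r0 = 0.05, r_decay = 3, r_inf = 0.01)
  expect_equal(retraction_fraction(pf, 1e6), 0.01)
})

test_that("retraction that would empty the mask raises a dynamics error", {
  m <- make_disc(8, 1, c(32L, 32L))
  expect_error(step_cycle(m, dynamics_params(r0 = 1, r_decay = 5), 1, 0),
               "dynamics error")
})

test_that("protrusion adds area at the configured rates with exact bookkeeping", {
  m <- make_disc()
  p <- dynamics_params(p_T = 0.01, p_A0 = 0.005, p_A_tau = 10, noise_sigma = 0.3)
  out <- step_cycle(m, p, 1, relax_time = 10, seed = 3)
  lg <- attr(out, "cycle_log")
  a0 <- spreading_area(m)
  expect_lt(abs(lg$protrusion_T_um2 / (0.01 * 10 * a0) - 1), 0.05)
  expect_lt(abs(lg$protrusion_A_um2 / (0.005 * 10 * a0) - 1), 0.05)
  # mass bookkeeping is exact in pixels
  expect_equal(spreading_area(out) - a0,
               lg$protrusion_T_um2 + lg$protrusion_A_um2 - lg$retraction_area_um2)
  # axial rate decays with cumulative stretching time
  out2 <- step_cycle(m, p, 1, relax_time = 10, cum_time_min = 20, seed = 3)
  lg2 <- attr(out2, "cycle_log")
  expect_lt(abs(lg2$protrusion_A_um2 / (0.005 * exp(-2) * 10 * a0) - 1), 0.05)
  expect_equal(lg2$protrusion_T_um2, lg$protrusion_T_um2)
})

test_that("step_cycle is deterministic and preserves the single component", {
  m <- make_disc(15, 1, c(96L, 96L))
  p <- dynamics_params(r0 = 0.05, r_decay = 3, p_T = 0.02, p_A0 = 0.01,
                       p_A_tau = 10, noise_sigma = 2)
  a <- step_cycle(m, p, 1, relax_time = 10, seed = 11)
  b <- step_cycle(m, p, 1, relax_time = 10, seed = 11)
  expect_identical(a$pixels, b$pixels)
  expect_equal(max(EBImage::bwlabel(a$pixels * 1)), 1)
  c_ <- step_cycle(m, p, 1, relax_time = 10, seed = 12)
  expect_false(identical(a$pixels, c_$pixels))
})

test_that("condition presets satisfy the documented ordering constraints", {
  ctrl <- preset_params("control")
  bleb <- preset_params("blebbistatin")
  noc <- preset_params("nocodazole")
  both <- preset_params("nocodazole_blebbistatin")
  expect_gt(noc$r0, ctrl$r0)
  expect_gte(noc$p_T, ctrl$p_T)
  expect_lt(bleb$r0, 0.01 * ctrl$r0 + 0.01)   # retraction suppressed
  expect_lt(bleb$p_T, 0.1 * ctrl$p_T)         # transverse protrusion suppressed
  expect_gt(bleb$p_A0 * exp(-90 / bleb$p_A_tau),
            ctrl$p_A0 * exp(-90 / ctrl$p_A_tau))  # sustained axial protrusion
  expect_gte(both$p_A0, bleb$p_A0)
  expect_lte(both$p_T, bleb$p_T)
  for (p in list(ctrl, bleb, noc, both)) {
    expect_true(p$r0 >= 0 && p$p_T >= 0 && p$p_A0 >= 0 &&
                  p$r_decay > 0 && p$p_A_tau > 0)
  }
  expect_error(preset_params("latrunculin"), "unknown condition")
})

test_that("under steady control cycling transverse length keeps growing", {
  pa <- preset_params("control")
  pr <- stretch_protocol("square", 0.15, 0.5, n_cycles = 30,
                         sample_points = schedule_at_cycles(1:30, "relaxation_end"))
  cell0 <- make_initial_cell(50, 0.06, 0.5, c(512L, 512L), seed = 5)
  sim <- simulate_timecourse(pr, pa, cell0, seed = 5)
  tl <- vapply(sim$frames, function(f) fit_rectangle(f)[["transverse_length"]],
               numeric(1))
  # after the retraction transient (~2 decay constants) growth never reverses
  post <- tl[seq(2 * ceiling(pa$r_decay), length(tl))]
  expect_true(all(diff(post) >= -cell0$pixel_size - 1e-9))
  expect_gt(tl[30], tl[8])
})

test_that("simulate_timecourse emits scheduled frames with exact phase semantics", {
  pa <- dynamics_params(r0 = 0.03, r_decay = 3, p_T = 2e-3, p_A0 = 1e-3,
                        p_A_tau = 10, noise_sigma = 0.3)
  sp <- schedule_at_cycles(1:3)
  pr <- stretch_protocol("square", 0.15, 0.5, n_cycles = 3, sample_points = sp)
  cell0 <- make_initial_cell(25, 0, 0.5, c(256L, 256L))
  sim <- simulate_timecourse(pr, pa, cell0, seed = 2)
  expect_length(sim$frames, 12)
  # schedule [pre_stretch of cycle 1] only -> the initial mask itself
  pr1 <- stretch_protocol("square", 0.15, 0.5, n_cycles = 3,
                          sample_points = data.frame(cycle = 1, phase = "pre_stretch"))
  one <- simulate_timecourse(pr1, pa, cell0, seed = 2)
  expect_length(one$frames, 1)
  expect_identical(one$frames[[1]]$pixels, cell0$pixels)
  # during_stretch differs from pre_stretch exactly by the substrate map
  pre <- find_cycle_phase(sim$frames, 1, "pre_stretch")
  dur <- find_cycle_phase(sim$frames, 1, "during_stretch")
  expect_identical(dur$pixels,
                   apply_substrate_strain(pre, 0.15, -0.15 * 0.15)$pixels)
  # ground truth balances the measured per-cycle area changes (<= 5%)
  gt <- sim$ground_truth
  rel <- vapply(1:3, function(n)
    spreading_area(find_cycle_phase(sim$frames, n, "relaxation_end")), numeric(1))
  a_before <- c(spreading_area(cell0), rel[1:2])
  expect_equal(rel - a_before,
               gt$protrusion_T_um2 + gt$protrusion_A_um2 - gt$retraction_area_um2)
  expect_lt(abs(gt$protrusion_T_um2[1] / (2e-3 * 1 * a_before[1]) - 1), 0.05)
  # determinism: bitwise-identical stacks for identical seeds
  sim2 <- simulate_timecourse(pr, pa, cell0, seed = 2)
  expect_identical(lapply(sim$frames, `[[`, "pixels"),
                   lapply(sim2$frames, `[[`, "pixels"))
  # schedule beyond n_cycles is a configuration error
  expect_error(stretch_protocol("square", 0.15, 0.5, n_cycles = 2,
                                sample_points = schedule_at_cycles(3)),
               "configuration error")
})

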