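# Grid/strain tests use a reduced 3x3 or 4x4 grid at 1 um/px so each
# render stays fast; the full-resolution default pattern is exercised in
# the acceptance suite.
small_grid <- grid_spec(square_side = 50, pitch = 100, n_rows = 3, n_cols = 3)

test_that("detect_grid recovers geometry of an ideal block pattern", {
  centers <- as.matrix(expand.grid(x = c(100, 200, 300), y = c(100, 200, 300)))
  img <- draw_block_grid(centers, 50, c(400L, 400L), 1)
  g <- detect_grid(img)
  expect_equal(g$n_detected, 9)
  expect_lt(abs(g$side_ax - 50), 1 + 1e-9)
  expect_lt(abs(g$side_tr - 50), 1 + 1e-9)
  expect_lt(abs(g$pitch_ax - 100), 0.5)
  expect_lt(abs(g$pitch_tr - 100), 0.5)
  # centers sorted row-major
  expect_true(all(diff(g$centers[1:3, "x"]) > 0))
  expect_lt(diff(range(g$centers[1:3, "y"])), 1)
})

test_that("detect_grid rejects blanks, border squares, and area outliers", {
  expect_error(detect_grid(micropattern_image(matrix(0, 64, 64), 1)),
               "detection error")
  # one square clipped by the border is excluded
  centers <- as.matrix(expand.grid(x = c(20, 150, 280), y = c(100, 200, 300)))
  img <- draw_block_grid(centers, 50, c(400L, 400L), 1)  # x=20 col touches border
  g <- detect_grid(img)
  expect_equal(g$n_detected, 6)
  # a fused double-size component is an area outlier and is excluded
  centers2 <- as.matrix(expand.grid(x = c(100, 200, 300), y = c(100, 200, 300)))
  img2 <- draw_block_grid(rbind(centers2, c(330, 100)), 50, c(400L, 400L), 1)
  expect_equal(detect_grid(img2)$n_detected, 8)
})

test_that("bead-rendered micropattern round-trips through the detector", {
  ref <- make_micropattern(small_grid, 0, 0, 0, pixel_size = 1, seed = 3)
  g <- detect_grid(ref)
  expect_equal(g$n_detected, 9)
  expect_lt(abs(g$side_ax - 50), 2)
  expect_lt(abs(g$pitch_ax - 100), 1)
  expect_lt(abs(g$pitch_tr - 100), 1)
})

test_that("measure_strain recovers applied affine strain from grid pairs", {
  ref <- make_micropattern(small_grid, 0, 0, 0, pixel_size = 1, seed = 3)
  gref <- detect_grid(ref)
  expect_equal(measure_strain(gref, gref)$eps_ax, 0)
  expect_equal(measure_strain(gref, gref)$eps_tr, 0)
  st <- make_micropattern(small_grid, 0.15, -0.0225, 0, pixel_size = 1, seed = 3)
  sm <- measure_strain(gref, detect_grid(st))
  expect_lt(abs(sm$eps_ax - 0.15), 0.005)
  expect_lt(abs(sm$ratio - 0.15), 0.01)
  # 10 um center-to-center error bound scaled: axial spacing at 10% strain
  st2 <- make_micropattern(small_grid, 0.10, 0, 0, pixel_size = 1, seed = 3)
  g2 <- detect_grid(st2)
  expect_lt(abs(g2$pitch_ax - 110), 1)
  # unmatched grids -> pairing error
  g4 <- detect_grid(draw_block_grid(
    as.matrix(expand.grid(x = c(100, 200), y = c(100, 200))), 50, c(300L, 300L), 1))
  expect_error(measure_strain(gref, g4), "pairing error")
})

test_that("measured strain is linear, symmetric and monotone in applied strain", {
  commanded <- c(0.05, 0.10, 0.15, 0.20)
  gref <- detect_grid(make_micropattern(small_grid, 0, 0, 0, pixel_size = 1, seed = 3))
  meas <- lapply(commanded, function(e) {
    img <- make_micropattern(small_grid, e, -0.15 * e, 0, pixel_size = 1, seed = 3)
    measure_strain(gref, detect_grid(img))
  })
  ax <- vapply(meas, `[[`, numeric(1), "eps_ax")
  expect_true(all(diff(ax) > 0))                     # monotone
  for (i in seq_along(commanded)) {                  # round trip, ~1px/extent
    expect_lt(abs(ax[i] - commanded[i]), 1 / 200)
  }
  fit <- strain_linearity(commanded, meas)
  expect_lt(abs(fit$axial["slope"] - 1), 0.02)
  expect_gt(fit$axial["r_squared"], 0.999)
  expect_gte(fit$axial["slope"] / fit$transverse["slope"], 6)
  # swapping ref and stretched negates the strain to first order
  g15 <- detect_grid(make_micropattern(small_grid, 0.15, -0.0225, 0,
                                       pixel_size = 1, seed = 3))
  fwd <- measure_strain(gref, g15)$eps_ax
  bwd <- measure_strain(g15, gref)$eps_ax
  expect_lt(abs(fwd + bwd), fwd^2 + 0.002)
  # constant measured values give slope 0
  const <- replicate(4, meas[[1]], simplify = FALSE)
  expect_equal(unname(strain_linearity(commanded, const)$axial["slope"]), 0,
               tolerance = 1e-12)
  expect_error(strain_linearity(commanded[1:3], meas), "lengths differ")
})

test_that("residual strain is zero for identical frames and recovers offsets", {
  gref <- detect_grid(make_micropattern(small_grid, 0, 0, 0, pixel_size = 1, seed = 3))
  expect_equal(residual_strain(gref, gref)$eps_ax, 0)
  # injected 1% residual axial strain is recovered
  g1 <- detect_grid(make_micropattern(small_grid, 0.01, 0, 0, pixel_size = 1, seed = 3))
  expect_lt(abs(residual_strain(gref, g1)$eps_ax - 0.01), 0.002)
  # independent bead-noise draws of an ideally elastic pair: tiny residual
  a <- detect_grid(make_micropattern(small_grid, 0, 0, 0.1, pixel_size = 1, seed = 10))
  b <- detect_grid(make_micropattern(small_grid, 0, 0, 0.1, pixel_size = 1, seed = 20))
  expect_lt(100 * abs(residual_strain(a, b)$eps_ax), 0.72)
})

test_that("micropattern images round-trip through 16-bit TIFF", {
  img <- make_micropattern(small_grid, 0, 0, 0, pixel_size = 1, seed = 3)
  path <- tempfile(fileext = ".tif")
  write_micropattern_tiff(img, path)
  rt <- read_micropattern_tiff(path, pixel_size = 1)
  expect_equal(dim(rt$pixels), dim(img$pixels))
  g1 <- detect_grid(img); g2 <- detect_grid(rt)
  expect_equal(g1$n_detected, g2$n_detected)
  expect_lt(abs(g1$pitch_ax - g2$pitch_ax), 0.1)
  unlink(path)
})
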