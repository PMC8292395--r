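test_that("difference_map is the exact set difference for binary masks", {
  a <- make_disc(10, 1, c(64L, 64L)); a$time <- 0
  b <- make_disc(12, 1, c(64L, 64L)); b$time <- 1
  d <- difference_map(a, b)
  expect_true(all(d$labels %in% c(-1L, 0L, 1L)))
  expect_equal(sum(d$labels == -1L), 0)                    # pure dilation
  expect_equal(sum(d$labels == 1L), sum(b$pixels) - sum(a$pixels))
  expect_true(all(difference_map(a, a_later(a))$labels == 0L))
})

test_that("difference_map is antisymmetric and matches the set-algebra oracle", {
  for (s in 1:4) {
    f1 <- random_blob(s); f1$time <- 0
    f2 <- random_blob(s + 100); f2$time <- 1
    d12 <- difference_map(f1, f2)$labels
    d21 <- difference_map(a_later(f2), f1_at(f1, 3))$labels
    expect_identical(d12, -d21)
    oracle <- matrix(0L, 64, 64)
    oracle[f2$pixels & !f1$pixels] <- 1L
    oracle[f1$pixels & !f2$pixels] <- -1L
    expect_identical(d12, oracle)
  }
})

test_that("difference_map rejects invalid pairs and supports intensity mode", {
  a <- make_disc(10, 1, c(64L, 64L))
  b <- make_disc(10, 1, c(80L, 80L)); b$time <- 1
  expect_error(difference_map(a, b), "shape")
  i1 <- matrix(0, 32, 32); i2 <- i1; i2[10:15, 10:15] <- 1
  expect_error(difference_map(i1, i2), "intensity_threshold")
  d <- difference_map(i1, i2, intensity_threshold = 0.5)
  expect_equal(sum(d$labels == 1L), 36)
})

test_that("quadrant partition follows the diagonal-sector geometry", {
  # disc centred off the pixel-lattice symmetry point, so diagonal tie
  # pixels (which go to the axial sectors) are absent
  m <- rasterize_ellipse(20, 20, 0, shape = c(63L, 64L), pixel_size = 1)
  part <- partition_quadrants(m)
  # total function over the frame
  expect_equal(sum(tabulate(part$labels, 4)), length(part$labels))
  # a pixel well along +stretch axis from the centroid is axial_plus
  ci <- round(part$centroid["y"]); cj <- round(part$centroid["x"] + 10)
  expect_equal(part$labels[ci, cj], 1L)
  # four quadrant-restricted areas of a centred disc agree within 2%
  areas <- vapply(1:4, function(q) sum(m$pixels & part$labels == q), numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.02)
})

test_that("quadrant labels match the brute-force per-pixel classification", {
  for (s in c(3, 17)) {
    m <- random_blob(s)
    part <- partition_quadrants(m)
    oracle <- brute_quadrant(m)
    lev <- c("axial_plus", "axial_minus", "transverse_plus", "transverse_minus")
    expect_identical(lev[part$labels], as.vector(oracle))
  }
})

test_that("net_area_change integrates and normalizes per quadrant", {
  m <- make_disc(20, 1, c(64L, 64L)); m$time <- 0
  part <- partition_quadrants(m)
  # all-zero difference
  z <- net_area_change(difference_map(m, a_later(m)), part, spreading_area(m))
  expect_true(all(z$net == 0) && all(z$protrusion == 0) && all(z$retraction == 0))
  # uniform 1-pixel erosion: net < 0 in all quadrants, equal within 10%
  er <- m
  er$pixels <- as.matrix(EBImage::erode(m$pixels * 1, EBImage::makeBrush(3, "diamond"))) > 0.5
  er$time <- 1
  qc <- net_area_change(difference_map(m, er), part, spreading_area(m))
  expect_true(all(qc$net < 0))
  expect_lt(diff(range(qc$net)) / abs(mean(qc$net)), 0.10)
  # conservation: sum of net * norm_area equals the total pixel-area change
  expect_equal(sum(qc$net) * qc$norm_area,
               (sum(er$pixels) - sum(m$pixels)) * m$pixel_size^2)
  expect_error(net_area_change(difference_map(m, er), part, 0), "norm_area")
})

test_that("transverse-restricted dilation registers only in transverse quadrants", {
  m <- make_disc(15, 1, c(64L, 64L)); m$time <- 0
  part <- partition_quadrants(m)
  grown <- m; grown$time <- 1
  add <- which(!m$pixels & (part$labels == 3L | part$labels == 4L))
  ring <- intersect(add, which(as.matrix(
    EBImage::dilate(m$pixels * 1, EBImage::makeBrush(5, "diamond"))) > 0.5))
  grown$pixels[ring] <- TRUE
  qc <- net_area_change(difference_map(m, grown), part, spreading_area(m))
  expect_true(all(qc$net[c("transverse_plus", "transverse_minus")] > 0))
  expect_equal(unname(qc$net[c("axial_plus", "axial_minus")]), c(0, 0))
})

test_that("cycle_response_profile pools quadrants and flags missing frames", {
  # null dynamics: three identical frames at one checkpoint
  m <- make_disc(15, 1, c(64L, 64L))
  fr <- lapply(1:3, function(k) {
    f <- m; f$time <- k; f$cycle_index <- 1L
    f$phase_tag <- c("pre_stretch", "post_release", "relaxation_end")[k]
    f
  })
  prof <- cycle_response_profile(fr, 1)
  expect_equal(nrow(prof), 4)  # 2 pair types x 2 pooled quadrants
  expect_true(all(prof$value == 0))
  expect_error(cycle_response_profile(fr, 2), "schedule error")
})
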