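test_that("reference frame is the brightest-cytoplasm frame, earliest on ties", {
  d <- array(0, dim = c(3, 1, 1, 8, 8))
  d[1, 1, 1, , ] <- 10; d[2, 1, 1, , ] <- 20; d[3, 1, 1, , ] <- 15
  st <- image_stack(d, 0.1)
  roi <- full_roi(c(8L, 8L))
  expect_equal(select_reference_frame(st, roi, 1), 2L)
  d[3, 1, 1, , ] <- 20  # tie between frames 2 and 3
  expect_equal(select_reference_frame(image_stack(d, 0.1), roi, 1), 2L)
  d1 <- array(7, dim = c(1, 1, 1, 8, 8))
  expect_equal(select_reference_frame(image_stack(d1, 0.1), roi, 1), 1L)
})

test_that("background statistics use the sample (n-1) standard deviation", {
  fr <- toy_frame(c(4L, 4L), bg = 100)
  expect_equal(estimate_background(fr, matrix(TRUE, 4, 4)),
               list(mean = 100, sd = 0))
  fr2 <- matrix(c(90, 110), 1, 2)
  bg <- estimate_background(fr2, matrix(TRUE, 1, 2))
  expect_equal(bg$mean, 100)
  expect_equal(bg$sd, sqrt(((90 - 100)^2 + (110 - 100)^2) / 1))  # 14.1421...
  one <- matrix(TRUE, 1, 1)
  expect_error(estimate_background(matrix(5, 1, 1), one), "SD undefined")
})

test_that("threshold is mean plus k standard deviations", {
  expect_equal(compute_threshold(100, 10, 2.5), 125)
  expect_equal(compute_threshold(100, 0, 2.5), 100)
  expect_equal(compute_threshold(0, 1, 0), 0)
  expect_equal(compute_threshold(100, 10), 125)  # default k = 2.5
  expect_error(compute_threshold(1, -1), "sd")
})

test_that("auto-selected background region avoids bright objects", {
  set.seed(4)
  p <- sim_params(seed = 4)
  sim <- simulate_cell(p)
  fr <- get_frame(sim$stack, 1, "polyQ")
  region <- select_background_region(fr, sim$roi, sim$stack$pixel_size_um)
  bg <- estimate_background(fr, region)
  expect_lt(abs(bg$mean - p$bg_mean) / p$bg_mean, 0.01)
  expect_lt(abs(bg$sd - p$bg_sd) / p$bg_sd, 0.10)
})

test_that("2D segmentation applies strict threshold, 8-connectivity and size filter", {
  fr <- toy_frame()
  expect_equal(segment_2d(fr, NULL, 0.5, 16)$n_objects, 0L)
  fr[5:9, 5:9] <- 10    # 25 px, survives
  fr[20:22, 20:22] <- 10  # 9 px, filtered
  seg <- segment_2d(fr, NULL, 5, 16)
  expect_equal(seg$n_objects, 1L)
  expect_equal(sum(seg$labels > 0), 25L)
  # strict inequality: pixels exactly at threshold are background
  expect_equal(segment_2d(fr, NULL, 10, 1)$n_objects, 0L)
  # diagonal contact is one object under 8-connectivity
  fr2 <- toy_frame()
  fr2[5, 5] <- 10; fr2[6, 6] <- 10
  expect_equal(segment_2d(fr2, NULL, 5, 1)$n_objects, 1L)
  # boundary of the filter: n = min passes, n = min - 1 fails
  fr3 <- toy_frame(); fr3[5:8, 5:8] <- 10  # 16 px
  expect_equal(segment_2d(fr3, NULL, 5, 16)$n_objects, 1L)
  expect_equal(segment_2d(fr3, NULL, 5, 17)$n_objects, 0L)
})

test_that("3D segmentation uses 26-connectivity and the voxel filter", {
  vol <- array(0, dim = c(6, 8, 8))
  expect_equal(segment_3d(vol, NULL, 0.5, 64)$n_objects, 0L)
  vol[2:5, 2:5, 2:5] <- 10  # 64-voxel cube
  seg <- segment_3d(vol, NULL, 5, 64)
  expect_equal(seg$n_objects, 1L)
  expect_equal(sum(seg$labels > 0), 64L)
  expect_equal(segment_3d(vol, NULL, 5, 65)$n_objects, 0L)
  # 3D diagonal contact joins under 26-connectivity
  vol2 <- array(0, dim = c(4, 4, 4))
  vol2[1, 1, 1] <- 10; vol2[2, 2, 2] <- 10
  expect_equal(segment_3d(vol2, NULL, 5, 1)$n_objects, 1L)
  expect_error(segment_3d(array(0, dim = c(1, 8, 8)), NULL, 5, 64),
               "segment_2d")
})

test_that("raising threshold or minimum size never grows objects", {
  set.seed(9)
  fr <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  fr[10:20, 10:20] <- 200
  fr[40:44, 40:44] <- 160
  thresholds <- c(120, 140, 160, 180)
  counts <- integer(0); totals <- integer(0)
  for (th in thresholds) {
    seg <- segment_2d(fr, NULL, th, 4)
    counts <- c(counts, seg$n_objects)
    totals <- c(totals, sum(seg$labels > 0))
  }
  expect_true(all(diff(totals) <= 0))
  sizes_prev <- Inf
  for (ms in c(1, 16, 64, 200)) {
    seg <- segment_2d(fr, NULL, 120, ms)
    if (seg$n_objects > 0) {
      expect_true(all(tabulate(seg$labels[seg$labels > 0],
                               seg$n_objects) >= ms))
    }
    expect_lte(seg$n_objects, sizes_prev)
    sizes_prev <- seg$n_objects
  }
})

test_that("object records carry physical units, circularity and intensities", {
  fr <- toy_frame(c(32L, 32L))
  fr[5:8, 5:8] <- 10  # 16 px square
  seg <- segment_2d(fr, NULL, 5, 16)
  rec <- measure_objects(seg, pixel_size_um = 0.0851,
                         intensity = list(raw = matrix(1, 32, 32)))
  expect_equal(rec$n_px, 16L)
  expect_equal(rec$area_um2, 16 * 0.0851^2)      # 0.11587 ~ 0.116 um^2
  expect_equal(rec$area_um2, 0.116, tolerance = 0.003)
  expect_equal(rec$intensity_raw, 16)            # all-ones image: sum = n_px
  # a discretized disk has circularity ~1
  m <- disk_mask(c(64L, 64L), 32, 32, 10)
  seg2 <- segment_2d(matrix(10 * m, 64, 64), NULL, 5, 16)
  rec2 <- measure_objects(seg2, pixel_size_um = 1)
  expect_gt(rec2$circularity, 0.9)
  expect_lt(rec2$circularity, 1.1)
  expect_equal(rec2$equivalent_radius_um, 10, tolerance = 0.05)
  # centroid in micrometres
  expect_equal(rec$centroid_y_um, (mean(5:8) - 0.5) * 0.0851)
})

test_that("2D area and 3D volume of one synthetic sphere are consistent", {
  r <- 8
  sh <- c(24L, 24L, 24L)
  zz <- array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), dim = sh)
  yy <- aperm(zz, c(2, 1, 3)); xx <- aperm(zz, c(3, 2, 1))
  sphere <- (zz - 12)^2 + (yy - 12)^2 + (xx - 12)^2 <= r^2
  seg3 <- segment_3d(array(10 * sphere, dim = sh), NULL, 5, 64)
  rec3 <- measure_objects(seg3, pixel_size_um = 1, z_step_um = 1)
  # equatorial cross-section
  seg2 <- segment_2d(matrix(10 * sphere[12, , ], 24, 24), NULL, 5, 16)
  rec2 <- measure_objects(seg2, pixel_size_um = 1)
  expect_equal(rec3$volume_um3, (4 / 3) * r * rec2$area_um2, tolerance = 0.1)
})

test_that("noise-free sharp-rendered stacks are recovered object for object", {
  p <- clean_params(seed = 21, n_aggregates = 12, adsorption = FALSE,
                    n_condensates = 0)
  sim <- simulate_cell(p)
  px <- sim$stack$pixel_size_um
  truth1 <- subset(sim$truth$objects, frame == 1 & type == "aggregate")
  fr <- get_frame(sim$stack, 1, "polyQ")
  seg <- segment_2d(fr, sim$roi, p$bg_mean, min_area_px = 1)
  rec <- measure_objects(seg, pixel_size_um = px)
  big <- truth1[truth1$area_um2 >= 0.2, ]
  expect_equal(seg$n_objects, nrow(truth1))
  for (i in seq_len(nrow(big))) {
    dists <- sqrt((rec$centroid_y_um - big$y_um[i])^2 +
                    (rec$centroid_x_um - big$x_um[i])^2)
    j <- which.min(dists)
    expect_lt(dists[j], px)                         # centroid within 1 px
    expect_lt(abs(rec$area_um2[j] - big$area_um2[i]) / big$area_um2[i], 0.2)
  }
})

test_that("segment_stack estimates one threshold and measures all channels", {
  p <- sim_params(seed = 5)
  sim <- simulate_cell(p)
  out <- segment_stack(sim$stack, sim$roi, "polyQ", frames = 1L)
  expect_gt(out$threshold, p$bg_mean)
  expect_true(all(c("area_um2", "intensity_p62", "intensity_polyQ") %in%
                    names(out$objects)))
  expect_gt(nrow(out$objects), 0)
})
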