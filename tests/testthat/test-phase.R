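test_that("intensity-concentration conversion is linear and invertible", {
  calib <- calibration_factors(slope = c(egfp = 1000, mch = 500),
                               offset = c(egfp = 0, mch = 50))
  expect_equal(intensity_to_concentration(2500, "egfp", calib), 2.5)
  expect_equal(intensity_to_concentration(50, "mch", calib), 0)
  conc <- 3.7
  I <- conc * 500 + 50
  expect_equal(intensity_to_concentration(I, "mch", calib), conc)
  expect_error(intensity_to_concentration(10, "nope", calib), "calibration")
  expect_error(intensity_to_concentration(10, "mch", calib), "offset")
})

test_that("phase point computes 24-mer core concentration and valence", {
  pp <- phase_point(24, 10)
  expect_equal(pp$c_core, 1)
  expect_equal(pp$valence, 10)
  expect_equal(phase_point(12, 0.5)$valence, 1)
  # joint rescaling leaves valence unchanged and doubles the core
  a <- phase_point(3, 7); b <- phase_point(6, 14)
  expect_equal(b$valence, a$valence)
  expect_equal(b$c_core, 2 * a$c_core)
  expect_error(phase_point(0, 1), "positive")
})

test_that("cytoplasmic patch has ~10 um^2 and recovers known concentrations", {
  for (px in c(0.0851, 0.15, 0.2)) {
    n <- max(2, round(sqrt(10) / px))
    expect_lt(abs((n * px)^2 - 10) / 10, 0.2)
  }
  p <- sim_params(seed = 18)
  ps <- simulate_phase_stack(TRUE, params = p)
  out <- cytoplasm_intensity(ps$stack, ps$roi)
  expect_equal(attr(out, "frame"), 1L)
  # uniform cytoplasm + background: slope-calibrated recovery within 5%
  calib <- calibration_factors(slope = c(p62 = 50), offset = c(p62 = p$bg_mean))
  conc <- intensity_to_concentration(out[["p62"]], "p62", calib)
  expect_lt(abs(conc - p$cytoplasm_level / 50) / (p$cytoplasm_level / 50), 0.05)
  # uniform pre-activation frame: the patch mean is the frame value
  d <- array(7, dim = c(2, 1, 1, 64, 64))
  st <- image_stack(d, 0.1, light_schedule = list(c(2, 2)))
  expect_equal(unname(cytoplasm_intensity(st, full_roi(c(64L, 64L)))[1]), 7)
})

test_that("condensation classifier needs texture gain plus a circular object", {
  # identical pre/post frames: ratio 1, not condensed
  set.seed(2)
  fr <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  d <- array(0, dim = c(2, 1, 1, 64, 64))
  d[1, 1, 1, , ] <- fr; d[2, 1, 1, , ] <- fr
  st <- image_stack(d, 0.1, channel_names = "p62",
                    light_schedule = list(c(2, 2)))
  roi <- full_roi(c(64L, 64L))
  out <- classify_condensation(st, roi, "p62")
  expect_false(out$condensed)
  expect_equal(out$cv_ratio, 1)
  # uniform gain x2 does not fake condensation (CV is gain-invariant)
  d[2, 1, 1, , ] <- 2 * fr
  out2 <- classify_condensation(image_stack(d, 0.1, channel_names = "p62",
                                            light_schedule = list(c(2, 2))),
                                roi, "p62")
  expect_equal(out2$cv_ratio, 1, tolerance = 1e-9)
  expect_false(out2$condensed)
  expect_error(
    classify_condensation(image_stack(d, 0.1, channel_names = "p62",
                                      light_schedule = list(c(1, 2))), roi),
    "pre-activation")
})

test_that("droplet and no-droplet cells are classified correctly across seeds", {
  wrong <- 0L
  for (s in 1:10) {
    p <- sim_params(seed = s)
    yes <- simulate_phase_stack(TRUE, params = p)
    no <- simulate_phase_stack(FALSE, params = p)
    if (!classify_condensation(yes$stack, yes$roi, "p62")$condensed) wrong <- wrong + 1L
    if (classify_condensation(no$stack, no$roi, "p62")$condensed) wrong <- wrong + 1L
  }
  expect_equal(wrong, 0L)
})

test_that("cell-wide classification distinguishes droplets from irregular recruitment", {
  p <- sim_params(seed = 23)
  yes <- simulate_phase_stack(TRUE, n_droplets = 4, params = p)
  out <- classify_cellwide(yes$stack, yes$roi, "p62")
  expect_equal(out$class, "droplet_condensation")
  expect_gte(out$n_droplets, 2)
  # p62 on elongated low-circularity shapes only: no droplet condensation
  irr <- simulate_phase_stack(TRUE, n_droplets = 3, irregular = TRUE, params = p)
  outi <- classify_cellwide(irr$stack, irr$roi, "p62")
  expect_equal(outi$class, "no_droplet_condensation")
  # empty activation response
  empty <- simulate_phase_stack(FALSE, params = p)
  expect_equal(classify_cellwide(empty$stack, empty$roi, "p62")$class,
               "no_droplet_condensation")
})

test_that("phase boundary fit recovers K and accuracy on separable data", {
  set.seed(41)
  pts <- simulate_titration(400, K = 1)
  fit <- fit_phase_boundary(pts)
  expect_equal(fit$accuracy, 1)
  expect_lt(abs(fit$K_hat - 1), 0.25)
  # shuffled labels: accuracy near 0.5 (binomial 95% band at n = 400)
  shuf <- pts
  shuf$condensed <- sample(shuf$condensed)
  fs <- fit_phase_boundary(shuf)
  expect_lt(abs(fs$accuracy - 0.5), 1.96 * sqrt(0.25 / 400) + 0.05)
  # single-class input errors
  allc <- pts[pts$condensed, ]
  expect_error(fit_phase_boundary(allc), "both")
  expect_error(fit_phase_boundary(pts[1:5, ]), ">= 10")
})

test_that("valence invariance and boundary homogeneity hold on fitted points", {
  set.seed(43)
  pts <- simulate_titration(100, K = 1)
  pp <- phase_point(pts$c_core * 24, pts$valence * pts$c_core)
  expect_equal(pp$valence, pts$valence)
  pp2 <- phase_point(pts$c_core * 48, pts$valence * pts$c_core * 2)
  expect_equal(pp2$valence, pts$valence)
})

test_that("boundary comparison detects a real shift and not a null one", {
  set.seed(47)
  a <- simulate_titration(400, K = 1)
  b <- simulate_titration(400, K = 4)
  cmp <- compare_boundaries(a, b, B = 200)
  expect_true(cmp$shifted)
  expect_lt(abs(cmp$log_ratio - log(4)) / log(4), 0.3)
  expect_false(cmp$flagged)
  # identical sets: no shift
  null_cmp <- compare_boundaries(a, a, B = 200)
  expect_false(null_cmp$shifted)
  expect_lte(null_cmp$ci[1], 0)
  expect_gte(null_cmp$ci[2], 0)
})
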