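test_that("pair PCC matches the hand-computed Pearson formula", {
  # 2x2 images: the union region is exactly the four listed pixels
  mk <- function(v) matrix(v, 2, 2)
  mask <- matrix(TRUE, 2, 2)
  a <- mk(c(1, 0, 1, 0))
  expect_equal(pair_pcc(a, 2 * a, mask, mask, min_px = 4)$pcc, 1)
  expect_equal(pair_pcc(a, -a + 5, mask, mask, min_px = 4)$pcc, -1)
  b <- mk(c(1, 0, 0, 1))
  # by hand: both means 0.5, cross products (.5)(.5)+(-.5)(-.5)+(.5)(-.5)+(-.5)(.5) = 0
  expect_equal(pair_pcc(a, b, mask, mask, min_px = 4)$pcc, 0)
})

test_that("PCC is invariant under affine rescaling of either channel", {
  set.seed(14)
  img <- matrix(runif(400, 0, 100), 20, 20)
  maskA <- disk_mask(c(20L, 20L), 8, 8, 4)
  maskB <- disk_mask(c(20L, 20L), 12, 12, 4)
  other <- matrix(runif(400, 0, 100), 20, 20)
  base <- pair_pcc(img, other, maskA, maskB)$pcc
  for (i in 1:10) {
    gain <- runif(1, 0.1, 10); offs <- runif(1, -5, 50)
    expect_equal(pair_pcc(gain * img + offs, other, maskA, maskB)$pcc, base,
                 tolerance = 1e-12)
    expect_equal(pair_pcc(img, gain * other + offs, maskA, maskB)$pcc, base,
                 tolerance = 1e-12)
  }
})

test_that("PCC contact rule and degenerate regions are enforced", {
  maskA <- matrix(FALSE, 20, 20); maskA[2:4, 2:4] <- TRUE
  maskB <- matrix(FALSE, 20, 20); maskB[10:12, 10:12] <- TRUE
  img <- matrix(runif(400), 20, 20)
  expect_error(pair_pcc(img, img, maskA, maskB), "not in physical contact")
  # a 1-px gap closes after both masks dilate by 1 px: in contact
  maskC <- matrix(FALSE, 20, 20); maskC[2:4, 7:9] <- TRUE
  maskD2 <- matrix(FALSE, 20, 20); maskD2[2:4, 11:13] <- TRUE
  expect_s3_class(pair_pcc(img, img, maskC, maskD2), "data.frame")
  # a 2-px gap keeps the dilated masks apart: not in contact
  maskD <- matrix(FALSE, 20, 20); maskD[2:4, 12:14] <- TRUE
  expect_error(pair_pcc(img, img, maskC, maskD), "not in physical contact")
  # constant channel: undefined (flagged NA), never 0
  flat <- matrix(5, 20, 20)
  r <- pair_pcc(flat, img, maskC, maskD2)
  expect_true(is.na(r$pcc))
  expect_true(r$undefined)
})

test_that("PCC-versus-size binning averages within radius bins", {
  pairs <- data.frame(radius_um = c(0.5, 0.6, 1.5, 1.6), pcc = 0.7)
  out <- pcc_vs_size(pairs, breaks = c(0, 1, 2))
  expect_equal(out$mean_pcc, c(0.7, 0.7))
  expect_equal(out$se, c(0, 0))
  single <- pcc_vs_size(data.frame(radius_um = 0.5, pcc = 0.4), c(0, 1))
  expect_true(is.na(single$se))
  set.seed(3)
  r <- runif(200, 0.2, 3)
  sim_pairs <- data.frame(radius_um = r,
                          pcc = pmin(0.3 + 0.2 * r + rnorm(200, 0, 0.04), 1))
  curve <- pcc_vs_size(sim_pairs, breaks = seq(0, 3, by = 0.5))
  expect_true(all(diff(curve$mean_pcc) > 0))
  expect_gt(cor(curve$bin_center_um, curve$mean_pcc, method = "spearman"), 0)
})

test_that("integrated intensity curves are normalized to each channel maximum", {
  obj <- data.frame(object_id = 1:4, area_um2 = c(1, 2, 3, 4),
                    intensity_ub = c(10, 20, 30, 40),
                    intensity_p62 = c(5, 10, 20, 80))
  out <- integrated_intensity_vs_size(obj)
  expect_equal(max(out$norm_ub), 1)
  expect_equal(max(out$norm_p62), 1)
  # intensity proportional to area: normalized curve is area / max(area)
  expect_equal(out$norm_ub, obj$area_um2 / 4)
  one <- integrated_intensity_vs_size(obj[1, ])
  expect_equal(one$norm_ub, 1)
  obj$intensity_ub <- 0
  expect_error(integrated_intensity_vs_size(obj), "zero maximum")
})

test_that("radial profile is flat on uniform images and peaks at a ring", {
  img <- matrix(7, 64, 64)
  cond <- data.frame(y_um = 32, x_um = 32, radius_um = 10)
  rp <- radial_profile(img, cond, pixel_size_um = 1)
  expect_lt(diff(range(rp$mean, na.rm = TRUE)), 1e-9)
  # bright annulus exactly at r = R
  ring <- matrix(0, 64, 64)
  yy <- row(ring); xx <- col(ring)
  rr <- sqrt((yy - 32.5)^2 + (xx - 32.5)^2)
  ring[abs(rr - 10) < 1] <- 100
  rp2 <- radial_profile(ring, data.frame(y_um = 32, x_um = 32, radius_um = 10),
                        pixel_size_um = 1)
  expect_equal(profile_peak(rp2), 0.95, tolerance = 0.051)
  # condensate centered outside the ROI is skipped with a warning
  roi <- matrix(FALSE, 64, 64); roi[1:20, 1:20] <- TRUE
  expect_warning(
    radial_profile(ring, data.frame(y_um = c(10, 32), x_um = c(10, 32),
                                    radius_um = c(3, 10)),
                   roi = cell_roi("c", roi), pixel_size_um = 1),
    "skipped")
})

test_that("interface adsorption shows as a rim peak; no adsorption shows none", {
  sim <- simulate_cell(sim_params(seed = 7))
  t_end <- sim$stack$light_schedule[[1]][2]
  cond <- subset(sim$truth$objects, frame == t_end & type == "condensate")
  rp <- radial_profile(get_frame(sim$stack, t_end, "polyQ"),
                       data.frame(y_um = cond$y_um, x_um = cond$x_um,
                                  radius_um = cond$radius_um),
                       roi = sim$roi, pixel_size_um = sim$stack$pixel_size_um)
  expect_lte(abs(profile_peak(rp) - 0.95), 0.1 + 1e-9)  # within 1 bin of r/R = 1
  # interface signal dominates the condensate core by >= 2x
  iface <- rp$r_rel >= 0.9 & rp$r_rel <= 1.1
  core <- rp$r_rel <= 0.5
  expect_gt(mean(rp$mean[iface]), 2 * mean(rp$mean[core]))

  simoff <- simulate_cell(sim_params(seed = 7, adsorption = FALSE))
  condo <- subset(simoff$truth$objects, frame == t_end & type == "condensate")
  rpo <- radial_profile(get_frame(simoff$stack, t_end, "polyQ"),
                        data.frame(y_um = condo$y_um, x_um = condo$x_um,
                                   radius_um = condo$radius_um),
                        roi = simoff$roi,
                        pixel_size_um = simoff$stack$pixel_size_um)
  band <- rpo$r_rel >= 0.8 & rpo$r_rel <= 1.2
  excess <- rpo$mean[band] - mean(rpo$mean)
  expect_true(all(excess <= 2 * rpo$se[band]))
})
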