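#!/usr/bin/env Rscript
# Interface analyses: radial intensity profile of the aggregate channel
# around condensates (adsorption on vs. off), pairwise PCC between the two
# channels for object pairs in contact binned by aggregate radius, and
# integrated intensity versus aggregate size.

suppressPackageStartupMessages(library(condagg))
dir.create("results", showWarnings = FALSE)

profile_of <- function(adsorption) {
  sim <- simulate_cell(sim_params(seed = 7L, adsorption = adsorption))
  t_end <- sim$stack$light_schedule[[1]][2]
  cond <- sim$truth$objects
  cond <- cond[cond$frame == t_end & cond$type == "condensate", ]
  radial_profile(get_frame(sim$stack, t_end, "polyQ"),
                 data.frame(y_um = cond$y_um, x_um = cond$x_um,
                            radius_um = cond$radius_um),
                 roi = sim$roi, pixel_size_um = sim$stack$pixel_size_um)
}
rp_on <- profile_of(TRUE)
rp_off <- profile_of(FALSE)
rp_on$condition <- "adsorption"
rp_off$condition <- "no_adsorption"
write_results(rbind(as.data.frame(rp_on), as.data.frame(rp_off)),
              "results/radial_profiles.csv")
message(sprintf(
  "Radial profile peaks at r/R = %.2f with adsorption (interface/core ratio %.1fx); no rim peak without it (peak at %.2f).",
  profile_peak(rp_on),
  mean(rp_on$mean[rp_on$r_rel >= 0.9 & rp_on$r_rel <= 1.1]) /
    mean(rp_on$mean[rp_on$r_rel <= 0.5]),
  profile_peak(rp_off)))

## ---- PCC versus aggregate size --------------------------------------------
# Pairs on a simulated two-channel frame: the condensate channel wets large
# aggregates more (ubiquitin-rich surfaces), so PCC rises with radius.
set.seed(5005)
pairs <- vector("list", 47L)
for (i in seq_along(pairs)) {
  r_um <- exp(runif(1, log(0.3), log(2.5)))
  shape <- c(48L, 48L); px <- 0.0851
  r_px <- r_um / px
  maskA <- matrix(FALSE, shape[1], shape[2])
  yy <- row(maskA); xx <- col(maskA)
  maskA <- (yy - 24)^2 + (xx - 24)^2 <= r_px^2
  imgA <- 200 + 600 * maskA + matrix(rnorm(prod(shape), 0, 20), shape[1])
  # p62 coverage of the aggregate grows with its size
  coverage <- plogis(3 * log(r_um / 0.8))
  cover_mask <- maskA & (yy <= 24 - r_px + 2 * r_px * coverage + 1)
  imgB <- 200 + 500 * cover_mask + matrix(rnorm(prod(shape), 0, 20), shape[1])
  pairs[[i]] <- pair_pcc(imgA, imgB, maskA, cover_mask | maskA,
                         radius_um = r_um)
}
pairs <- do.call(rbind, pairs)
curve <- pcc_vs_size(pairs, breaks = c(0.2, 0.6, 1.0, 1.6, 2.6))
write_results(curve, "results/pcc_vs_size.csv")
message(sprintf(
  "PCC rises from %.2f (smallest aggregates) to %.2f (largest) over %d pairs.",
  curve$mean_pcc[1], curve$mean_pcc[nrow(curve)], nrow(pairs)))

## ---- integrated intensity versus size -------------------------------------
sim <- simulate_cell(sim_params(seed = 7L))
seg <- segment_stack(sim$stack, sim$roi, "polyQ", frames = 1L)
ii <- integrated_intensity_vs_size(seg$objects)
write_results(ii, "results/integrated_intensity_vs_size.csv")
message(sprintf(
  "Integrated intensities normalized to channel maxima over %d aggregates (max = 1 by construction).",
  nrow(ii)))
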