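#!/usr/bin/env Rscript
# Interface-mediated coarsening across condensation/dissolution cycles:
# mean area of small (< 5 um^2) aggregates at the first frame of each
# condensation cycle, averaged over 10 cells, with rim merging enabled
# versus disabled, plus the bulk-intensity conservation check.

suppressPackageStartupMessages(library(condagg))
dir.create("results", showWarnings = FALSE)

n_cells <- 10L
on_reports <- off_reports <- vector("list", n_cells)
bulk_dev <- numeric(n_cells)
for (i in seq_len(n_cells)) {
  sim <- simulate_cell(sim_params(seed = i))
  on_reports[[i]] <- cycle_coarsening(sim$stack, sim$roi)
  bulk_dev[i] <- max(abs(bulk_intensity_trace(sim$stack, sim$roi, "polyQ") - 1))
  simoff <- simulate_cell(sim_params(seed = i, merge_on_dissolution = FALSE,
                                     adsorption = FALSE))
  off_reports[[i]] <- cycle_coarsening(simoff$stack, simoff$roi)
}

rep_on <- cycle_report(on_reports)
rep_off <- cycle_report(off_reports)
rep_on$condition <- "merging"
rep_off$condition <- "no_merging"
write_results(rbind(rep_on, rep_off), "results/cycle_coarsening.csv")

monotone <- vapply(on_reports, function(r)
  all(diff(r$mean_small_area_um2) >= -1e-9), TRUE)
message(sprintf(
  "Merging on: mean small-aggregate area %.2f -> %.2f um^2 over %d cycles; monotone in %d/%d cells.",
  rep_on$mean_small_area_um2[1], tail(rep_on$mean_small_area_um2, 1),
  nrow(rep_on), sum(monotone), n_cells))
message(sprintf(
  "Merging off: %.2f -> %.2f um^2 (no trend).",
  rep_off$mean_small_area_um2[1], tail(rep_off$mean_small_area_um2, 1)))
message(sprintf(
  "Bulk aggregate intensity deviates from 1 by at most %.2f%% per cell (conservation).",
  100 * max(bulk_dev)))
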