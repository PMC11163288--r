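# condagg

Quantitative image analysis of the interplay between liquid-like protein
condensates and solid-like protein aggregates in living cells.

## The problem

p62/SQSTM1 is an oligomeric autophagy receptor that forms liquid-like
condensates and is enriched in pathological inclusions such as mutant
Huntingtin polyQ aggregates. With an optogenetic "corelet" scaffold (an
iLID-decorated 24-mer core that captures sspB-fused p62 under blue light),
p62 condensation can be switched on and off inside a cell. Doing so reveals
a mechanical interplay: newly formed condensates collect small polyQ
aggregates on their interfaces, and when the condensates dissolve, the
rim-bound aggregates are driven together and merge — interface-mediated
coarsening. Large, heavily ubiquitinated aggregates in turn soak up free
p62 and suppress further condensation, shifting the cell's phase boundary.

`condagg` implements the measurement pipeline for this system, and a
synthetic-microscopy generator that embodies the mechanism, so that every
stage can be validated against known ground truth without any deposited
images:

* **Segmentation** — background-region statistics, intensity threshold
  `mean + k·SD` (default `k = 2.5`), 8-/26-connectivity components,
  minimum-size filters of 16 px (0.116 µm²) in 2D and 64 voxels
  (0.116 µm³) in 3D, and per-object measurements in physical units
  (area, centroid, equivalent radius, circularity `4πA/P²`, integrated
  intensities).
* **Aggregate statistics** — per-cell complementary cumulative size
  distributions `P(S ≥ s)` averaged across cells with SE; aggregation
  propensity vs. concentration; mean small-aggregate (< 5 µm²) area at the
  first frame of each condensation cycle; bulk-intensity conservation
  traces.
* **Interface colocalization** — radial intensity profiles in normalized
  radius `r/R` around condensates (bin width 0.1, range [0, 2]); Pearson
  correlation between channels over 1-px-dilated object-pair masks, binned
  by aggregate radius; integrated intensity vs. size normalized to channel
  maxima.
* **FRAP kinetics** — fractional-recovery normalization and a
  single-exponential fit `F(t) = (1 − d) + d·m·(1 − e^{−kt})` with the
  bleach depth `d` fixed from the first post-bleach sample, returning the
  mobile fraction `m` and rate `k`, with an explicit no-recovery regime.
* **Phase diagrams** — FCS-calibrated conversion of intensities to
  concentrations, core concentration `C = c_monomer/24` and valence
  `V = c_sspB/C`, per-cell condensation classification (gain-invariant
  coefficient-of-variation ratio plus droplet circularity), logistic
  boundary fitting in `(log C, log V)` with the hyperbola `V·C = K` as its
  interpretable special case, and a bootstrap shift test between
  conditions.
* **Synthetic microscopy** — calibrated two-channel time-lapse stacks with
  condensates that nucleate/grow under a light schedule and dissolve
  without it, aggregates that adsorb to condensate rims and merge on
  dissolution (area and intensity conserved exactly), Gaussian PSF and
  detector noise, and a complete ground-truth record (positions, sizes,
  merge lineage, bulk totals).

## Worked example

The `analysis/` directory holds the full workflow as numbered scripts
(`01_simulate.R` … `07_phase_diagram.R`), each writing its tables under
`results/`. Running stages 4 and 7 prints, for example:

```
Merging on: mean small-aggregate area 0.72 -> 1.52 um^2 over 4 cycles; monotone in 9/10 cells.
Merging off: 0.72 -> 0.72 um^2 (no trend).
Bulk aggregate intensity deviates from 1 by at most 0.24% per cell (conservation).

Control: accuracy 1.00, K_hat 1.01. Large-aggregate condition: accuracy 1.00, K_hat 4.02.
Boundary shift log(K_l/K_c) = 1.38 (95% CI 1.31..1.49): shifted (condensation suppressed).
```

The first block is the coarsening signature: with rim merging enabled, the
mean area of small aggregates roughly doubles over three
condensation/dissolution cycles while the bulk aggregate signal stays
constant (material is rearranged, not created); with merging disabled the
means stay flat. The second block shows the phase-boundary readout: a
400-cell titration with true boundary `V·C = 1` is classified perfectly and
`K` is recovered within a few percent, and a condition with a four-fold
higher condensation threshold is flagged as a significant boundary shift.

A minimal in-R session:

```r
library(condagg)
sim <- simulate_cell(sim_params(seed = 1))          # stack + ROI + ground truth
cc  <- cycle_coarsening(sim$stack, sim$roi)          # per-cycle small-agg areas
fit <- fit_recovery(simulate_frap_trace(0.4, 0.05))  # mobile fraction 0.6, k 0.05/s
```

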