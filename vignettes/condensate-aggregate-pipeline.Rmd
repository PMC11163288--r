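---
title: "Measuring interface-mediated aggregate coarsening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interface-mediated aggregate coarsening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condagg)
```

This vignette explains the models, conventions and design choices behind
`condagg`. The package quantifies the interaction between light-inducible
p62 condensates (liquid-like droplets) and polyQ protein aggregates
(solid-like inclusions) in two-channel live-cell microscopy, and ships a
synthetic-microscopy generator embodying the mechanism under study so that
every measurement can be validated against exact ground truth.

## The mechanistic picture

The analyses target a three-step mechanism. (1) Under blue light, an
optogenetic 24-mer scaffold oligomerizes a p62 construct and droplet-like
condensates nucleate and grow in the cytoplasm. (2) Small aggregates near a
condensate are captured at its interface and accumulate there over minutes,
visible as a rim of aggregate signal at the condensate periphery. (3) When
the light is switched off the condensate dissolves, and the aggregates it
held on its shrinking interface are driven together and merge into a larger
aggregate. Repeated condensation/dissolution cycles therefore coarsen the
aggregate population without changing the total amount of aggregate
material. Separately, very large, heavily ubiquitinated aggregates bind
soluble p62 and suppress further condensation, which shows up as a shifted
phase boundary.

## Data model and conventions

An `image_stack` holds a `(t, z, c, y, x)` array of nonnegative float
intensities plus physical geometry (`pixel_size_um`, optional `z_step_um`),
channel names, the frame interval, and the blue-light schedule as a list of
`c(on, off)` frame pairs. All public geometry is in micrometres; pixel/unit
conversion is centralized in `area_to_px()` and friends. One stated
convention is used throughout: frame and pixel indices are 1-based with
inclusive interval ends, the native R convention; pixel centers sit at
`(i - 0.5) * pixel_size_um` from the array origin. Intensities are
unit-agnostic floats — no assumption about detector bit depth is made.

Stacks are stored as multi-page 32-bit float TIFF with a YAML sidecar
(`pixel_size_um`, `z_step_um`, `frame_interval_s`, `light_schedule`,
`channel_names`, dimensions, and an `intensity_scale` used to map raw
values into the [0, 1] range TIFF floats require). The sidecar exists
because image metadata alone cannot carry the light schedule.

The default pixel size of 0.0851 µm is chosen so that the two standard
minimum-size filters are mutually consistent: 16 pixels equal 0.116 µm²
and, with 0.25 µm optical sections, 64 voxels equal 0.116 µm³. This is an
internal consistency check of the printed constants, and
`area_to_px(0.116, 0.0851)` reproduces 16 exactly.

## Segmentation

The threshold procedure mirrors standard practice for these experiments:

1. pick the **reference frame** with the maximum mean cytoplasmic
   brightness (ties break to the earliest frame);
2. estimate the background **mean and sample SD** (n − 1 denominator) in a
   cytoplasmic region free of condensates and aggregates;
3. threshold at `mean + k·SD` with `k = 2.5`, computed **once** and applied
   to all relevant frames (not re-estimated per frame);
4. keep connected components (8-connectivity in 2D, 26 in 3D) of pixels
   **strictly above** the threshold, with at least 16 pixels (2D) or 64
   voxels (3D).

Where an interactive analysis hand-picks the background region, the package
uses a reproducible proxy: the ROI is tiled into 2 × 2 µm tiles, and among
tiles whose 99th intensity percentile lies below the ROI median plus one
SD (i.e. tiles without bright objects) the lowest-mean tile is selected,
falling back to the overall lowest-mean tile. Strict inequality at the
threshold is a convention; ties are measure-zero for float data.
Connectivity is stated explicitly because it fixes object counts:
4-connectivity labelers split diagonally touching objects, so labeling is
implemented on an explicit pixel-adjacency graph (igraph components), which
also provides 26-connectivity in 3D.

Per-object measurements are physical: `area_um2 = n_px · pixel_size_um²`,
`volume_um3 = n_vox · pixel_size_um² · z_step_um`, equivalent radius of the
equal-area disk / equal-volume sphere, and circularity `4πA/P²`. The
perimeter uses chain-code tracing with Vossepoel–Smeulders weights (0.980
per straight step, 1.406 per diagonal, −0.091 per corner): with raw
boundary-pixel counts a digitized disk's circularity is biased ~20% high,
while the weighted estimate keeps it within a few percent of 1. Circularity
up to 1.1 is tolerated as discretization error.

For 2D analyses of multi-section data the default is the single reference
section; maximum projection is available but not default, since the choice
is not fixed by the procedure being reproduced.

## The synthetic-microscopy generator

`simulate_cell()` renders one elliptical cell through a light schedule of
three condensation/dissolution cycles plus a final condensation (5 light-on
and 3 light-off frames per cycle by default, one frame per minute — a
compressed rendering of 30-min activations and 15-min dissolutions).
Defaults describe the study conditions: Gaussian detector background
(mean 200, SD 20), 25 aggregates with lognormal areas
(`meanlog = log 0.3`, `sdlog = 0.5` µm² — a broad, mostly sub-µm²
population, matching the "many small aggregates" regime in which interface
clustering is observed), aggregate brightness 800 above background, three
condensates per activation nucleating at 0.4 µm radius and growing
0.15 µm/frame, exponential dissolution with a one-frame time constant, a
1.5 µm interface-capture distance, a Gaussian PSF of σ = 0.1 µm (a
realistic confocal width at this pixel size), and additive Gaussian noise
applied last.

Design choices worth stating:

* **Shapes are disks** (aggregates) and sharp-rimmed disks (condensates)
  before PSF blur — the simplest geometry whose ground truth is exact.
* **Adsorption is instantaneous repositioning** to the nearest rim point,
  beginning the frame *after* nucleation (interfacial accumulation takes
  minutes; the first frame of each cycle therefore shows free aggregates,
  which is also the analysis frame). Attached aggregates track the rim as
  it grows or shrinks; no transport law is simulated because only the end
  state matters to the measurements.
* **Merging conserves area and intensity**: when a condensate dissolves
  (radius below half the nucleation radius), all rim-attached aggregates
  merge into one aggregate of summed area at their area-weighted centroid,
  and the lineage is recorded.
* **Rendering conserves intensity exactly**: each aggregate disk's pixel
  values are scaled so its integrated intensity equals
  `amplitude · area / pixel_area` regardless of sub-pixel position, and the
  Gaussian blur is sum-preserving, so in a noise-free stack the bulk
  aggregate signal is constant to float precision by construction. This is
  what makes the conservation analysis a sharp test.
* **Placement enforces resolvability**: distinct aggregates are placed with
  at least 0.8 µm of boundary clearance (and condensate nucleation sites
  with two capture distances). Two touching solid aggregates are physically
  one aggregate, so ground truth that counts them separately while the
  rendering fuses them would be internally inconsistent.
* A **maximum rim occupancy** parameter exists (default unbounded) because
  interfaces plausibly saturate, but no measured value is available.

What the generator deliberately does not emulate: reaction–diffusion or
mean-field phase-separation physics, aggregate nucleation or growth from
solution, 3D rendering beyond stacked sections, photobleaching during
ordinary imaging, and diffuse cytoplasmic aggregate-channel signal.
Passing tests on this synthetic data therefore demonstrate that the
*measurement pipeline* faithfully quantifies the modeled mechanism — not
that real cells obey the model, and not robustness to real-world artifacts
(uneven illumination, motion, out-of-focus light) beyond Gaussian noise
and blur.

A known systematic of threshold segmentation is visible in the synthetic
data and worth keeping in mind with real data too: because the PSF tail of
a bright object crosses a `mean + 2.5 SD` threshold well outside the true
boundary, detected areas exceed true areas (by roughly 2× at default
brightness). The coarsening statistics are ratios and trends across cycles,
which this bias largely cancels out of.

## Size statistics and coarsening

Per-cell CCDFs are the empirical survival `P(S ≥ s)` at the observed sizes;
cross-cell averaging evaluates each cell's step function on the union grid
and reports mean and `SE = SD/√n_cells` — averaging is over cells, never
pooled aggregates, so each cell carries equal weight. Step evaluation
preserves each cell's empirical function exactly, which is why it was
chosen over smoothing or linear interpolation.

The cycle analysis segments the aggregate channel at the first frame of
each condensation interval and reports the mean area of aggregates below
the 5 µm² small-aggregate cutoff (10 µm² marks "large" aggregates in the
phase-diagram analyses; both cutoffs are 2D areas and live in
`pipeline_config()`). Condensate areas, where needed, use the same
threshold rule — nothing in the procedure distinguishes the channels.
Conservation is checked with `bulk_intensity_trace()`: the ROI-summed
aggregate signal per frame, normalized to frame 1.

## Interface profiling and colocalization

`radial_profile()` bins pixel intensities by normalized radius `r/R` around
each condensate (bin width 0.1 over [0, 2] — enough to resolve an
interface peak for condensates of ≳10 px radius), normalizes each
condensate's profile to its own maximum by default (a global-scale option
exists; the per-condensate choice weights every condensate equally), and
averages with SE across condensates. Interface adsorption appears as a
peak in the bin containing `r/R = 1`.

`pair_pcc()` operationalizes "objects in physical contact" as: the two
object masks, each dilated by one pixel, share at least one pixel (an
original gap of at most one pixel). The Pearson coefficient is computed
over the **union of the dilated masks** — not the whole cell and not a
bounding box — because the object pair is the unit of analysis; whole-cell
pixels would dilute the statistic with background correlation. A region
with zero variance in either channel yields `NA` with an `undefined` flag,
never 0, since "no information" and "no correlation" are different
statements. Regions below 8 pixels are rejected by default.

## FRAP

Traces are normalized to the first pre-bleach sample. The recovery model is
the minimal single exponential
`F(t) = (1 − d) + d·m·(1 − e^{−k(t − t0)})` with the bleach depth
`d = 1 − F(t0)` fixed from the first post-bleach point, leaving two free
parameters: the mobile fraction `m` and rate `k` (fit with
Levenberg–Marquardt least squares; `m` is started from the late-recovery
amplitude and `k` from the half-recovery time). One exponential is enough
to separate the three regimes the experiments distinguish — no recovery
(solid aggregates), partial recovery (condensates), full recovery — and
anything richer would be uninterpretable on 120 s traces with ~1 s
sampling. A trace whose recovery amplitude is indistinguishable from its
noise returns `m = 0` with `k` flagged unidentifiable rather than an
arbitrary rate. No photofading correction is applied because no reference
region is part of the protocol; a reference-trace argument is the natural
extension point. Whether traces should be background-subtracted before
normalization is unspecified in the protocol; the package normalizes raw
traces and leaves subtraction to the caller.

## Phase diagrams

Intensities convert to concentrations linearly through FCS-derived
calibration factors, `µM = (I − offset)/slope`. The diagram axes are the
core concentration `C = c_monomer/24` (the scaffold is a 24-mer, and the
calibration is per monomer) and the valence `V = c_sspB/C`, the average
number of sspB-fused clients available per core. The ratio direction is
fixed by reading "average valence of each core" as client-per-core; the
text defining the ratio is ambiguous in isolation, and this reading is the
one under which "valence" has its usual meaning.

Condensation is classified per cell from a pre-activation frame and the
end of the first activation interval: the coefficient of variation
(SD/mean) of ROI intensity must rise by at least 1.5× **and** at least one
detected object must have circularity ≥ 0.8. The CV ratio rather than the
raw SD ratio makes the metric invariant to illumination gain — a uniformly
brighter frame has a larger SD but unchanged texture. Cell-wide
classification (`classify_cellwide()`) calls `droplet_condensation` when at
least two circular objects appear during activation, following the
convention that the condensing regime is the one with multiple de novo
spherical condensates; because the opposite labeling convention also
appears in descriptions of this assay, the raw droplet counts are returned
so either can be applied.

The phase boundary is a logistic decision surface in
`(log C, log V)`. When the two slopes agree within 20% the boundary is the
hyperbola `V·C = K` and `K̂ = exp(−2β₀/(β₁+β₂))` is reported (the
symmetric form of the implied constant; with near-equal slopes it matches
either single-slope expression). The logistic form was chosen over fitting
the hyperbola directly because it degrades gracefully when the data do not
support the interpretable special case. Complete separation — expected for
a well-resolved binodal — makes the glm coefficients diverge in norm while
the boundary ratio stays stable; the fit suppresses the attendant warnings
deliberately and reports training accuracy alongside. Condition comparison
bootstraps cells within each condition (1000 resamples by default) and
reports a percentile CI on `log(K_b/K_a)`; "shifted" means the CI excludes
0, and resamples that lose a class are dropped, with a flag if they exceed
10%.

## Problem sizes and numerical choices

The test-suite and acceptance computations use the study-scale problem
sizes: 10 cells × 4 analysis frames for coarsening, 29-frame 224 × 224
two-channel stacks, 200 replicate FRAP traces at noise SD 0.02, 400-cell
titrations, and 100–1000 bootstrap resamples (the repeated null-calibration
loop uses 100–200 resamples per repeat; the detector's default stays at
1000). Degenerate inputs are errors, not silent defaults: empty ROIs,
single-pixel background regions (SD undefined), single-section input to
the 3D segmenter, traces with a nonpositive normalizer, single-class
boundary fits, and frame-1-zero bulk traces all fail loudly with the
reason.

## Known limitations

* Threshold segmentation inflates bright-object areas via the PSF tail
  (above); absolute areas should be compared only within a consistent
  imaging/threshold regime.
* No watershed splitting: aggregates closer than the blur scale merge into
  one detected object. The generator enforces resolvable placement; real
  dense fields will under-count.
* The FRAP model ignores diffusion geometry; `k` is an empirical rate, not
  a diffusion coefficient.
* Condensates and aggregates are identified per frame; there is no
  tracking across frames, so lineage exists only in simulator ground
  truth.
* The boundary-shift test compares the interpretable constant `K`; if two
  conditions differ in boundary *shape* rather than position, the log-ratio
  summarizes them only coarsely.
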