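---
title: "Methods: quantifying mitochondrial health from high-content images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitochondrial health from high-content images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

## Overview

`mitoscreen` quantifies three per-cell readouts of mitochondrial health
from multi-channel fluorescence images of well plates:

1. **Mitochondrial H2O2** — a boronate H2O2 probe (MitoPY1-like) forms
   bright speckles where hydrogen peroxide accumulates. The readout is
   the *colocalized-area fraction*: the area of detected speckles that
   overlaps the mitochondrial mask inside a cell, divided by that
   cell's mitochondrial-mask area. It lies in [0, 1] and rises with
   oxidative load.
2. **Mitochondrial membrane potential (MMP)** — a ratiometric carbocyanine
   dye (JC-10) accumulates as orange-fluorescent J-aggregates in
   polarized mitochondria and as green-fluorescent monomers in the
   cytosol of depolarized cells. The readout is the per-cell
   orange/green mean-intensity ratio over mutually masked regions; it
   falls as mitochondria depolarize.
3. **Mitochondrial morphology** — the membrane-potential-independent
   mitochondrial stain gives the network channel. Fragmentation is read
   from a grayscale *granular spectrum* (granulometry): the percentage
   of regional intensity removed by morphological erosion at increasing
   scales. Length is read from the skeleton: the maximal geodesic
   distance between skeleton endpoints of each mitochondrial object.

All intensities are normalized to [0, 1] at load time by the source bit
depth, so every threshold below is on that scale.

## Segmentation front end

All assays share one object hierarchy:

* **Primary objects (nuclei)** from the DNA stain: global three-class
  Otsu threshold with the middle intensity class assigned to the
  background (suppressing dim debris), hole filling, and an equivalent
  diameter window.
* **Secondary objects (cells)** by seeded propagation from the nuclei
  over the above-threshold region of the cell-body channel (the
  mitochondrial channel, or the green JC-10 channel for the MMP assay).
  A pixel joins the seed of minimal accumulated cost, where the step
  cost blends local intensity difference with a spatial regularization
  term `lambda`. `lambda = 0.05` by default; as `lambda` grows the
  dividing line between touching cells approaches the geometric
  midline (the nearest-seed partition in the limit).
* **Tertiary objects (cytoplasm)** as the per-label set difference
  cell minus nucleus. The area identity
  `area(cytoplasm) = area(cell) - area(cell ∩ nucleus)` holds exactly
  and is tested.
* **Filtering**: objects can be removed by area, eccentricity,
  intensity, or contact with the image border (incomplete cells).
  Default nucleus filters: area 100–10,000 px², eccentricity ≤ 0.95 —
  package defaults, scaled down for the reduced-size validation plates.

Conventions fixed across the package: 8-connectivity for components and
skeletons; labels are positive integers with 0 background, compacted to
`1..n` after every filtering step; pixel coordinates are 0-based
row/column indices in exported tables.

### Threshold methods

Histogram methods use a fixed 256-bin grid on [0, 1], making results
reproducible across camera bit depths. Two-class Otsu maximizes the
between-class variance over all cuts; three-class Otsu searches all cut
pairs exhaustively; the minimum cross-entropy (Li) threshold is the
fixed point of the classic two-means iteration. Where a histogram has an
empty gap between modes every cut in the gap classifies identically; the
implementation takes the first maximizer. Tests therefore compare
thresholds to exhaustive-search oracles *by the classification they
induce* (or within one bin).

Adaptive scope computes the chosen method per window-sized block
(default 51 px) and interpolates block-center values bilinearly to a
per-pixel grid, clamped to the spec's `bounds`. For speckle and
aggregate detection, blocks without structure would collapse into the
noise; unless the caller sets explicit bounds, the detection functions
clamp the adaptive grid from below at 70% of the global two-class Otsu
threshold and never below 0.05. The absolute floor reflects that these
detections run on enhancement-filtered channels whose true background is
near zero; it is what keeps a blank, noise-only field from yielding
spurious puncta while leaving real speckles (enhanced amplitude well
above 0.1) untouched.

## Assay details and parameter choices

**H2O2.** Speckles are enhanced by a white top-hat: the image minus its
grayscale opening with a Euclidean disc of radius
`ceiling(feature_size/2)`. `feature_size = 35` px equals the largest
accepted punctum diameter, so no valid punctum is suppressed. Detected
puncta (diameter 3–35 px) are assigned to the cell containing their
centroid; puncta whose centroid falls on background are dropped from
per-cell sums. The colocalized area uses the footprint of the puncta
related to the cell, intersected with the mitochondrial mask inside the
cell. The denominator is the cell's mitochondrial-mask area — this makes
the score a per-cell mitochondrial ROS burden in [0, 1]; a
puncta-area denominator is available via `denominator = "puncta"`.
Cells with no mitochondrial mask are excluded and counted, never
reported as zero.

**MMP.** J-aggregates are small bright dots (3–15 px) in the orange
channel. The monomer region of a cell is its secondary object from the
green channel. `A*` is the aggregate footprint clipped to the cell's
monomer region, and — reading "monomers masked by aggregates"
literally — `M*` is the monomer region clipped to the aggregate
footprint union. Under this literal reading `A*` and `M*` coincide
pixel-wise within a cell, so the ratio compares the two dyes over the
same pixels; whether the complement (green *outside* the aggregates) was
intended cannot be decided from the method description, so
`monomer_mask = "complement"` exposes the alternative. Mean (not
integrated) intensities make the ratio robust to region-size asymmetry,
and the per-cell ratio is exactly invariant to a common gain and exactly
proportional to an orange-only gain.

**Morphology.** The network channel is enhanced by Hessian tubeness:
Gaussian smoothing at `scale_sigma` (≈ half the tube width; default
1.5 px at full resolution, 0.9 px on the small validation plates), then
`|lambda2|` of the finite-difference Hessian where `lambda2` is the
more-negative eigenvalue, clamped to zero elsewhere and rescaled to
[0, 1]. Smoothing is what makes elongated ridges outscore isotropic
blobs of equal height. The mask is `enhanced >= max(Li threshold,
manual_floor)` with `manual_floor = 0.1` (a manual bound was part of the
original protocol; the published value is not stated), then objects of
diameter 3–100 px.

The granular spectrum is measured on the raw (illumination-corrected)
mitochondrial channel restricted to each cell's cytoplasm: optional
downsampling, background removal by subtracting the opening with a disc
of radius `element_size`, then repeated 3×3 erosion with morphological
reconstruction under the background-removed image;
`g_i = 100 (I_{i-1} - I_i) / I_0` is the percentage of intensity living
at granule scale `i`. Granulometry keys on the *minimum* dimension of a
structure: punctate fragments smaller than the tube width push intensity
into the first bins. The headline fragmentation number is
`fragmentation_percent` with `k = 1` (the smallest scale); `k` is a
plain configuration knob. Defaults `subsample = 0.25`,
`element_size = 10`, `L = 16` suit full-resolution images; the
validation-scale parameters use `subsample = 1`, `element_size = 5`
because the cell regions are already small.

Skeletons come from Zhang–Suen thinning; endpoints are skeleton pixels
with exactly one 8-connected neighbour. Geodesic steps weigh 1 (axial)
and √2 (diagonal), and a diagonal edge is only admitted when neither of
its two orthogonal stepping-stone pixels is on the skeleton — without
this rule a right-angle bend of two 10-px arms would measure
16 + √2 instead of 18, i.e. the path would cut the corner. An object's
length is the maximum endpoint-pair geodesic ("longest path");
`summary = "total"` instead sums the skeleton's spanning tree (total
branch length). Objects whose skeleton has fewer than two endpoints are
recorded with length 0 and flagged. Micrometre lengths are always
`px × pixel_size_um` (default 0.299 µm/px, configuration-overridable).

## The synthetic plate generator

Real validation imagery cannot ship with a package; instead the
generator renders plates with known ground truth. Each field contains
ellipsoidal nuclei, a cell body, and per cell a set of mitochondrial
tubes radiating from the nuclear rim, one per angular sector so tubes
remain resolvable. Three dose knobs drive the channels:

* `puncta_density` — expected Poisson count of H2O2 puncta per cell,
  placed on the tubes (dose proxy for an oxidant titration);
* `polarization` ∈ [0, 1] — orange aggregate amplitude scales with it,
  green cytosolic haze with `0.04 + 0.5 (1 − polarization)` (a small
  residual monomer fluorescence keeps the green channel segmentable in
  fully polarized cells, as in real JC-10 imagery);
* `fragmentation` ∈ [0, 1] — per-tube fission probability; a fragmented
  tube collapses into three punctate pieces, each smaller than the tube
  width, spread along its former path.

On top of the clean render: a 0.7-px Gaussian optics blur, a smooth
quadratic illumination bias, Poisson shot noise (photon scale 2000) plus
Gaussian read noise (σ = 0.005), and quantization to the design bit
depth with the same truncation rule the TIFF writer uses — so plates
written to disk reload bit-identically, and the same design and seed are
bit-reproducible.

What the generator does **not** emulate: cell-to-cell staining
heterogeneity beyond Poisson puncta counts, point-spread anisotropy and
confocal sectioning, autofluorescence, photobleaching, touching/clumped
nuclei, or debris. Passing the dose-trend tests therefore shows the
pipeline recovers generative structure under realistic noise and bias —
not that it is robust to every artifact of real plates. Declumping of
touching nuclei is deliberately not implemented (the filtering stage is
the only remedy); fields are generated with separated cells.

### Problem sizes

The built-in validation study (`run_dose_response_study()`) uses
256 × 256-px fields with proportionally scaled cells (4–6 per field,
cell radius 24–30 px), 3 conditions × 2 wells × 10 fields per plate and
10 independent plates; full-scale defaults (1080 px, 0.299 µm/px,
16-bit, 15–40 cells/field) match the acquisition geometry the package
targets. At the reduced scale the three trends are each supported by
roughly 400–600 cells per condition.

```{r, eval = FALSE}
study <- run_dose_response_study(seed = 1, n_seeds = 10)
dose_trend(study$h2o2, "h2o2_level")        # rising with puncta density
dose_trend(study$mmp, "mmp_ratio")          # falling with depolarization
dose_trend(study$morphology, "fragmentation_percent")  # rising
dose_trend(study$morphology, "mean_length_px")         # falling
```

## Statistics

Per-cell metrics pool within condition for inference — matching how
plate distributions are usually displayed — while per-well means are
also emitted so users can run well-level inference; the run log notes
that replicate wells on one plate are technical replicates. Summaries
report means with normal-approximation 95% CIs (`mean ± 1.96 SE`; CI
flagged undefined for singleton groups). Outliers are flagged by the
Tukey boxplot rule (1.5 × IQR beyond the quartiles, type-7 quantiles)
and reported, never auto-removed. Multi-group comparisons use one-way
ANOVA with Tukey's HSD; two-group comparisons use the equal-variance
Student t-test (the Welch test sits behind a flag). Significance stars
follow 0.05 / 0.01 / 0.001.

## Numerical notes and degenerate inputs

* Constant images make every histogram threshold degenerate: the
  constant is returned with a warning and the foreground is empty.
* The illumination fit falls back to an SVD pseudo-inverse (with a
  warning) on rank-deficient grids such as a single row. Corrected
  intensities are clipped at zero — negative fluorescence is
  meaningless and downstream thresholds assume non-negative input.
* Grayscale reconstruction uses Vincent's hybrid algorithm (raster
  scans plus a FIFO queue) in compiled code; tests pin it to a naive
  iterate-dilate-and-clip implementation to 1e-9.
* A seed entirely below the secondary threshold propagates to itself
  (with a warning); cells with an empty assay region are excluded and
  counted per field rather than contributing zeros.

## Known limitations

* Touching nuclei merge into one object (no watershed declumping).
* The colocalization metric is area-based by design; no
  intensity-weighted coefficients (Pearson, Manders) are provided.
* The granular spectrum is sensitive to the background-removal radius
  relative to structure width; at very low resolutions scales ≥ 2 blur
  together.
* Skeleton length for heavily branched networks reports the longest
  endpoint path by default, which underestimates total network extent —
  use `summary = "total"` when the total branch length is wanted.
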