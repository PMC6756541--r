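---
title: "Methods: simulation, segmentation, gating and enumeration in microhca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation, gating and enumeration in microhca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhca)
```

## The problem

High-content analysis (HCA) instruments image multi-well plates in several
fluorescence channels and extract quantitative features from every detected
object. Applied to bacteria, this turns a microscope into a counting and
phenotyping instrument: total and viable cells per mL from a handful of
imaged fields, antibiotic-induced morphology shifts, and strain identity of
single cells in mixed cultures. `microhca` implements that workflow end to
end at desk scale, with a seeded simulator standing in for the instrument so
that every stage can be validated against pixel-level ground truth.

## The synthetic imaging model

`generate_field()` emulates one imaged field of sparse, adherent,
mostly non-overlapping bacteria:

* **Shapes.** Cells are rendered as anti-aliased filled shapes from a
  backbone-plus-radius model: a point (coccus), a straight segment capped by
  semicircles (rod), a quadratic Bezier bend (curved rod), or a random-walk
  tube (filament). These four families cover the morphology range of common
  test organisms, from micrococci to hypha-like filaments, with few
  parameters.
* **Staining.** Each morphotype carries a mean signal per channel role
  (DAPI / FITC / Cy3) with lognormal cell-to-cell dispersion, and a
  `stain_coverage` fraction: the probability that a given cell takes the
  stain at all. Coverage below 1 in FITC reproduces the dye-resistant
  subpopulation that is visible with a general DNA stain (DAPI) but not
  with a SYTO-family dye, which is why detection combines both channels.
* **Viability.** Dead cells emit in the exclusion-dye channel (Cy3 role);
  live cells show only weak autofluorescence there. A field's
  `viable_fraction` sets the per-cell Bernoulli probability.
* **Camera.** Signal plus a flat background passes through Poisson shot
  noise, additive Gaussian read noise, and 16-bit clipping — the standard
  camera model.
* **Geometry.** The pixel size defaults to 0.065 um (a 6.5 um camera pixel
  behind a 100x objective). The default field is 256 x 256 px; tests use
  sizes between 64 and 320 px to balance realism against runtime.
* **Placement.** With overlap disallowed (the default — the protocol this
  models dilutes samples precisely to avoid overlapping objects), cells are
  placed by rejection sampling with a 2.5 px guard margin around each
  footprint so that thresholded masks of neighbouring cells do not fuse.
  Cells that cannot be placed after 250 tries are dropped in
  density mode (the crowded-well regime that dilution-linearity QC exists
  to catch) and raise an error in exact-count mode.
* **Reproducibility.** Every field derives its own RNG stream from
  (master seed, well, field), so any well can be regenerated independently
  and identical seeds give bit-identical images and truth.

What the simulator does *not* model: optical point-spread blur, 3-D
structure and defocus, photobleaching, uneven illumination, biofilm or
clump formation, and instrument-specific fixed-pattern noise. Passing
recovery tests on these images therefore demonstrates the correctness of
the pipeline's logic and arithmetic, not segmentation performance on real
instrument images, which are harder in ways the simulator deliberately
leaves out.

## Segmentation

Detection combines the requested channel roles by background-normalizing
each (local-median background at radius 15 px, well above a cell width,
then dividing the residual by its MAD) and taking the per-pixel maximum, so
a cell visible in any detection channel is visible in the combination.
The detection grid is thresholded at `threshold_k = 5` robust SDs above
background; 8-connected components become objects; components outside
[`min_area_px`, `max_area_px`] are rejected. The default minimum area is
the pixel area of a 0.5 um coccus — anything smaller is sub-bacterial
debris. `split_touching = TRUE` refines components with a
distance-transform watershed, the standard treatment for touching convex
cells; it is off by default because it can oversplit long filaments.
Coordinates are 0-based and row-major with pixel-centre convention.

## Morphometry

Per object: area, outer-boundary perimeter, form factor, second-moment
ellipse axes, skeleton end nodes, and per-channel mean, total and mode
density.

* **Perimeter.** The Moore outer boundary is traced through border-pixel
  centres; straight steps count 1 and diagonal steps 1.2674. The diagonal
  weight solves `E[cos(t) + (w - 1) sin(t)] = 1` for orientation `t`
  uniform on [0, 45 degrees], which makes the estimator unbiased for
  digitized circles while keeping axis-aligned rectangles exact (a 10 x 10
  square measures exactly 36).
* **Form factor** is `4 * pi * area / perimeter^2`: 1 for a circle,
  tending to 0 for a line. Discretization can push the raw ratio slightly
  above 1 for small round objects, so reported values are capped at 1.0;
  single-pixel objects are defined as 1.0 and QC-flagged rather than
  dividing by zero.
* **End nodes** count skeleton pixels (Zhang-Suen thinning) with exactly
  one 8-connected skeleton neighbour: 2 for a rod, 3 for a branched
  object, at most 1 for a compact blob. Objects with more than 3 end nodes
  are excluded as clumps or debris by `filter_objects()`.
* **Mode density** is the most frequent raw 16-bit value in the mask
  (bin width 1, ties toward the lower bin — the vendor definition is
  unpublished, so exactness beats guessing). Because whether the vendor
  value is background-corrected is also unstated, the table carries both
  the raw mode and a background-subtracted variant (mode minus the median
  of unlabelled pixels), and gating selects either.

## Viability gating and enumeration

Two gating chemistries are implemented:

* **Dye exclusion** (PI, SYTOX Orange): membrane-impermeant DNA dyes stain
  only dead cells, so viable objects lie at or below the cutoff. Cutoffs
  come from a heat-killed control of the same strain — by default the
  99.5th percentile of the dead-control intensity distribution, since the
  exact statistic used on the instrument is unstated; the percentile is a
  configuration parameter, and fixed manual cutoffs (100 for PI, 1000 for
  SYTOX Orange, applied to background-subtracted intensities) are
  available when no control exists.
* **Protein-synthesis incorporation** (HPG/CLICK): cells incorporating the
  methionine analog HPG acquire reporter signal, so viable objects lie
  strictly *above* the cutoff, set at the 90th percentile of the paired
  minus-HPG sample (`p90_cutoff()`). All percentiles use the
  linear-interpolation convention (R type 7), documented and fixed so that
  on n distinct values almost exactly 10% fall strictly above the P90.

By construction, 10% of plus-HPG objects exceed a P90 cutoff even with no
signal, so the corrected viable count is `n_A_v - 0.1 * n_A`, clamped to
[0, n_A]. (The alternative grouping `n_A - (n_A_v - 0.1 * n_A)` is kept
behind `rule = "alternative"` for auditability.) Because non-viable
objects exceed the cutoff at rate 0.1 and strongly labelled viable cells
at essentially 1, the expected exceedance fraction is `f + 0.1 (1 - f)`;
the corrected count therefore estimates `0.9 f`, and the reported
`viable_fraction_estimate` divides by 0.9 to recover `f` itself. This
debiasing is what lets a true fraction of 1.0 be recovered within 0.05,
which the raw correction cannot do (its bias at `f = 1` is −0.1).

Enumeration is plain arithmetic:
`cells/mL = counts x field_factor x dilution_factor x sampling_factor`,
with `field_factor = total possible fields / imaged fields` (650/9 = 72.22
for the 384-well default — computed, never hard-coded, which also settles
the 72.2-vs-72.22 rounding question) and `sampling_factor = 20` for a
50 uL sample. A dilution series is accepted only when the mean count per
dilution regresses on 1/dilution with R^2 above 0.95 over at least 3
dilutions; the fit is on counts vs 1/dilution rather than log-log to match
the linear-counts acceptance rule (log-log is available for the slope
diagnostics in the simulator tests). If the full series fails, the
dilution with the largest absolute residual is dropped and the fit
repeated while enough dilutions remain; enumeration averages cells/mL only
over accepted dilutions. Replicate summaries report the sample SD and
`%CV = 100 * SD / mean`.

## Strain identification

A bootstrap random forest is trained on per-object features of pure
cultures and applied per object to mixtures. The upstream software's
"default settings" are unpublished, so the reference configuration is: 100
trees, `floor(sqrt(p))` candidate features per split, unlimited depth,
bootstrap size equal to the training size — all exposed as arguments.
Partitioning is stratified 60%/20%/20% train/test/validation by strain with
largest-remainder rounding, reproducible per seed; strata below 5 objects
are refused. Features default to every numeric morphometry and intensity
column, excluding identifiers, QC flags, truth columns, and optionally the
gating channel when it would leak treatment (the published feature list is
unspecified, so both geometry-only and geometry-plus-intensity
configurations are runnable). Majority-vote ties break toward the
lexicographically lowest strain label so that reports are deterministic.
Per-strain identification rates are computed by re-applying the model to
the full single-strain tables; mixture composition is the frequency of
per-object most-probable labels.

## Numerical and design choices

* Percentile convention: linear interpolation (type 7), everywhere.
* 8-connectivity for components and skeleton neighbours; 4-connectivity is
  available for labelling but not used by the pipeline.
* Watershed splitting runs on the distance transform with tolerance 1.
* Degenerate inputs: empty fields, empty mixtures, zero means, single-pixel
  objects and saturated detection channels are all handled explicitly and
  QC-flagged rather than erroring mid-pipeline.
* The CSV feature table is the interchange format between stages; TIFFs are
  16-bit grayscale, one file per channel per field.

## Problem sizes used in the test suite

The suite validates statistical properties at sizes chosen to keep the
whole run comfortably reproducible on a laptop: segmentation recovery on
20 seeded 256 x 256 px fields of ~25 cells; enumeration recovery on 100
seeded count-level dilution series (4 dilutions x 3 replicates x 9
fields); HPG recovery at 5 true fractions x 20 seeds x 2000 objects;
classifier checks on ~20 rendered 320 x 320 px fields (~850 objects)
plus count-level feature simulations. Count-level series use the same
Poisson draws the renderer would, so skipping pixel rendering there
changes nothing statistically.

## Known limitations

* The perimeter estimator is tuned for convex-ish digital shapes; very
  small (< 30 px) thresholded objects can still overshoot a form factor of
  1 before capping.
* Watershed splitting and the end-node filter are heuristics; dense fields
  beyond the dilution-linearity regime are out of scope by design.
* The classifier is only as good as the feature table; morphologically
  identical strains are not separable by construction, as in the assay the
  package models.
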