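---
title: "Quantifying angiogenesis from color-coded vessel annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying angiogenesis from color-coded vessel annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angioquant)
```

## The measurement problem

In implantation models of vascularization, a tissue construct grows around a
central vascular bundle — an artery and a vein — and the question is how much
new vasculature has formed, where it sits relative to that bundle, and how
the answer differs between treatment groups. The raw data are histologic
cross sections in which every vessel profile has been painted by hand in a
reserved color: the central artery red, the central vein blue, and every
other vessel green, on a neutral background. Manual marking is deliberate:
deciding what counts as a vessel (wall, lumen, erythrocytes, staining) is a
histologist's judgement, and the software's job begins after it. The package
turns those annotations into five per-sample read-outs and a group-level
statistical comparison.

## Per-sample pipeline

1. **Read and calibrate** (`read_annotation_image`). The raster is decoded
   with its physical pixel size in µm/pixel (scans at 644 nm/pixel are a
   typical native calibration). Only a single isotropic scale is accepted.
2. **Resample** (`resample_image`) to a square working resolution, 2500 px
   by default. Interpolation is nearest-neighbor: any smoothing
   interpolation would blend the reserved colors into intermediate ones and
   corrupt class labels. The scale is multiplied by the resampling ratio, so
   physical extent is preserved. Non-square scans keep their aspect ratio
   and are padded to square with background; the square target is a
   convention, not data.
3. **Color split** (`color_split`). A pixel joins a class when each RGB
   channel lies within a tolerance (default 40) of the class's reference
   color (pure red/blue/green by default — annotation tools vary, so both
   colors and tolerance are configurable). The constructor rejects
   conventions whose reference colors are separated by less than twice the
   tolerance, which guarantees the three masks are disjoint.
4. **Detect and measure** (`detect_marks`). Every 8-connected component of
   each mask becomes one vessel mark; 8-connectivity is chosen because
   hand-painted strokes often touch only diagonally. Components smaller than
   `min_pixels` (default 4 at the 2500 px working size) are discarded as
   stray annotation pixels; `min_pixels = 0` keeps every painted pixel
   group. Each mark is measured by its pixel centroid, its pixel-count area
   (`area = pixel_count × scale²`, held exactly), and the axes of the
   moment-equivalent ellipse from the second central moments of the pixel
   set. A per-pixel variance of 1/12 px² is added per axis so the moments
   are those of the pixel squares rather than their centers; a single pixel
   then has axes 4·sqrt(1/12) ≈ 1.155 px instead of zero.
5. **Identify the central pair** (`identify_central_vessels`). The largest
   blue component is the central vein and the largest red one the central
   artery; additional blue/red components are demoted to capillaries with a
   warning. A sample with no blue mark cannot yield ingrowth distances: the
   function errors by default, while the pipeline flags the sample and
   continues with the distance-free metrics.

## The five read-out parameters

* **Total vessel count** — the number of capillary-class marks; the central
  artery and vein are excluded by definition.
* **Total perfused area** (mm²) — each mark's painted shape is expanded by a
  fixed radius (150 µm by default, a conventional oxygen-diffusion
  distance), and the area of the union is reported, overlaps counted once.
  The union is computed by thresholding a Euclidean distance transform of
  the mark raster — an exact-metric morphological dilation — on a canvas
  padded by the radius, so expansion is never clipped at the image border.
  The dilation expands the actual mark shape, not an equivalent disk. The
  central artery and vein are part of the union by default (the perfusion
  halo is drawn around *each* vessel), with `include_central = FALSE`
  available since the counterpart count excludes them; which convention is
  in force is recorded in the outputs.
* **Perfused-area vessel density** (vessels/mm²) — the exact per-sample
  quotient of the two numbers above, so `density × area = count` holds to
  machine precision. An empty sample has density 0 by convention.
* **Vessel ingrowth distance** (µm) — the Euclidean distance from each
  counted mark's centroid to the central vein's centroid, treating the vein
  as the origin of ingrowth. The artery-to-vein distance is computed and
  stored separately, never pooled.
* **Vessel diameter** (µm) — the minor axis of the mark's moment-equivalent
  ellipse, wall included. Oblique sectioning stretches only the major axis,
  so the minor axis is the robust diameter proxy.

Distribution-valued read-outs (distances, diameters) are additionally
histogrammed (`vessel_histogram`): diameter bins default to 10 µm over
0–300 µm and ingrowth bins to 250 µm over 0–5000 µm, with an optional
normalized variant (heights are fractions of the total count and sum to 1)
and a smoothed variant (centered moving average, default window 3 bins,
zero-padded at the edges, applied after normalization). The bin widths and
the moving-average smoother are package conventions — reasonable defaults
for capillary-dominated samples, all configurable.

## Group statistics

Group means are reported with the SEM (sample standard deviation over
√n; a group of one sample reports SEM 0 with a warning). Groups are compared
with the classical fixed-effects one-way ANOVA — F on (k−1, N−k) degrees of
freedom via `stats::oneway.test(var.equal = TRUE)` — at α = 0.05.

Post hoc pairwise comparisons use Duncan's multiple range test
(`duncan_posthoc`), written for this package because no installed package
provides it. Means are ranked; a comparison spanning r ranks is declared
significant when the mean difference exceeds

q(1 − α_r, r, df_within) · sqrt(MS_within / n_h),   α_r = 1 − (1 − α)^(r−1),

where q is the studentized-range quantile, α_r is Duncan's protection level,
and n_h is the harmonic mean of the two group sizes (the unequal-n rule; the
harmonic mean is noted in the output when sizes differ). A pair contained in
a wider non-significant range is never declared significant. Computing the
quantiles from the studentized-range distribution rather than printed tables
keeps the test reproducible at arbitrary degrees of freedom; the
protection-level quantiles reproduce Duncan's published 5% table at df = 20
(2.95/3.10/3.19 for r = 2/3/4) within rounding. For k = 2 the procedure
reduces exactly to the pooled-variance two-sample t-test, including unequal
sizes. Duncan's test natively yields decisions, not p-values, so per-pair
p-values are obtained by bisection over α (the smallest α at which the pair
is significant, clamped to [1e−5, 0.999]) and star levels code
p ≤ 0.05/0.01/0.001 as 1/2/3 stars. Each sample is treated as an independent
unit; missing values are dropped per metric, never imputed, and no
multiple-testing correction is applied across the five metrics.

## The synthetic generator

`generate_sample` renders what the analysis assumes: one centric vein (blue,
400 µm), one artery beside it (red, 250 µm), and a population of elliptical
green capillary marks on a white 2500 px / 1.6 µm-per-pixel canvas (a
4 × 4 mm cross section). Capillary minor-axis diameters are log-normal
(median 15 µm, σ_log 0.5, truncated to 5–300 µm) — an illustrative,
capillary-dominated choice, not a fitted distribution; centers are placed at
uniform radii (350–1800 µm) from the vein at uniform angles; the minor/major
axis ratio is uniform on (0.5, 1) and orientations are uniform. Placements
are rejection-sampled (1000 attempts per mark) so that distinct marks keep
at least 3 px of background between them and never overlap the central pair,
because the analysis equates one connected component with one vessel. Every
output is a pure function of the specification including its seed.
`generate_study` derives deterministic per-sample seeds from a study seed
and draws per-sample capillary counts from a Poisson distribution around
each group's mean, giving realistic between-sample variability.

What the generator does *not* emulate: touching or overlapping vessel
profiles (real annotations can merge two vessels into one blob), irregular
hand-drawn outlines, partially out-of-frame vessels, staining differences,
and anti-aliased annotation edges (available only as an option for testing
color tolerance). Passing the recovery suite therefore demonstrates the
correctness of the computational chain on clean annotations, not robustness
to annotation pathology.

## Numerical choices and validation problem sizes

* Rasterized union areas agree with closed-form disk, annulus and two-disk
  lens formulas within 1% at the scales used (≤ 2 µm/px); the residual error
  is the half-pixel boundary bias of rasterization.
* Axis measurement noise: for rasterized ellipses the moment axes recover
  generating parameters within 2% once the minor axis exceeds roughly
  15 px; at a 10 px minor axis the irreducible quantization jitter is about
  1% RMS with ~3% worst case, a property of binary rasterization rather
  than of the estimator (a least-squares subpixel coverage fit reaches the
  same floor). Diameters near the working resolution limit should be read
  with that granularity in mind.
* Detection completeness is validated on 50 synthetic samples of 20–250
  capillaries at the full 2500 px working resolution; ingrowth recovery on
  full-size samples; the engineered-effect power study (60 vs 170 mean
  capillaries, n = 10 per group) also runs at working resolution. The
  200-replicate null calibration of the full pipeline uses 512 px images at
  4 µm/px with proportionally larger capillaries — the calibration concerns
  the statistics, which are resolution-independent once detection is exact,
  and this keeps the suite's footprint proportionate. The ANOVA type-I
  calibration uses 2000 normal-theory replicates at k = 4, n = 10.
* Degenerate inputs: empty images yield empty tables and zero metrics (with
  flags); zero within-group variance raises a classed error rather than a
  spurious F; a positive count with zero perfused area is impossible by
  construction and treated as such.

## Known limitations

* The analysis is strictly 2-D, one mid-construct plane per sample; no
  serial-section registration or 3-D reconstruction.
* The 150 µm perfusion radius is a fixed convention approximating oxygen
  diffusion, not a physiological model.
* Duncan's test controls error less conservatively than Tukey's HSD by
  design; it is provided because it is the convention in this analysis
  lineage, not as a recommendation.
* Metrics from annotations made under a different color convention require
  explicitly configuring `color_convention`; the defaults assume pure RGB
  annotation colors.
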