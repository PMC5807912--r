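# angioquant

Spatial quantification of angiogenesis from color-coded vessel annotations
of histologic cross sections.

## What it does, and for whom

Implantation models of vascularization grow tissue around a central
vascular bundle and ask how much new vasculature formed, where it sits
relative to that bundle, and whether treatments differ. The input to this
package is the standard manual annotation of such sections: every vessel
profile painted in a reserved color — central artery **red**, central vein
**blue**, all other vessels **green** — plus the scan's µm/pixel
calibration. The package is for experimenters running such studies who need
reproducible per-sample metrics and group statistics without a hand-curated
spreadsheet pipeline.

Per sample, after resampling to a 2500 px working grid and splitting by
color, every painted mark is detected as one 8-connected component and
measured by its moment-equivalent ellipse. Five read-outs follow:

1. **Total vessel count** — capillary-class marks (central pair excluded).
2. **Total perfused area** — area of the union of all marks dilated by a
   fixed oxygen-diffusion radius r (150 µm default), overlaps counted once:
   `A = |⋃ᵢ (Mᵢ ⊕ B_r)|`, computed by thresholding a Euclidean distance
   transform of the mark raster.
3. **Vessel density** — count / perfused area (vessels/mm²), exact quotient.
4. **Ingrowth distance** — Euclidean distance from each mark's centroid to
   the central vein's centroid (µm), one per counted vessel.
5. **Vessel diameter** — minor axis of each mark's moment-equivalent
   ellipse (µm), robust to oblique sectioning.

Groups are summarized as mean ± SEM and compared by one-way ANOVA
(α = 0.05) with Duncan's multiple range post hoc test: a comparison
spanning r ranked means is significant when the difference exceeds
`q(1−α_r, r, df_w)·√(MS_w/n_h)` with protection level `α_r = 1−(1−α)^(r−1)`;
stars code p ≤ 0.05/0.01/0.001. A seeded synthetic annotation generator
with ground truth makes every stage testable without histology.

## Worked example

```r
library(angioquant)

# a synthetic sample: 120 capillaries around a central vein/artery pair,
# 2500 px at 1.6 um/px, seeded and fully reproducible
s <- generate_sample(sample_spec(n_capillaries = 120, seed = 7))
m <- run_sample(s$image, study_config(), sample_id = "demo")
print(m)
#> sample 'demo': 120 vessels, perfused area 6.785 mm^2, density 17.69 vessels/mm^2
#>   ingrowth distance: mean 1133 um (range 365.3-1784)
#>   diameter: median 15.93 um (perfusion radius 150 um)
```

All 120 generated marks were detected (the count equals the generator's
ground truth); the perfused area is the single-counted union of the 150 µm
halos, and density is its exact quotient with the count. A two-group study
with an engineered difference in mean capillary count:

```r
st <- generate_study(list(fibrin = list(n_capillaries = 60),
                          vegf20 = list(n_capillaries = 170)),
                     n_per_group = 4, seed = 42)
sm <- run_study(st, study_config(compute = "count"))
print(sm)
#> study summary: 8 samples, 2 groups (alpha = 0.05)
#> - total_vessel_count
#>     fibrin: 70.25 +/- 4.029 (SEM, n = 4)
#>     vegf20: 175.2 +/- 8.189 (SEM, n = 4)
#>     ANOVA F(1,6) = 132.4, p = 2.591e-05
#>     fibrin vs vegf20 *** (p = 2.58e-05)
```

Per-sample counts scatter around each group's mean (Poisson between-sample
variability), the groups separate decisively, and the Duncan comparison —
which for two groups is exactly the pooled t-test — flags the pair at three
stars. Real scans run the same way: `run_sample("scan.png", study_config(
scale = 0.644))`, or `run_study("manifest.csv", cfg, out_dir = "out")` with
a `filename,group` manifest, which writes per-vessel tables, per-sample and
per-group CSVs, pooled histograms, and a JSON study summary. A thin CLI
wrapper lives in `inst/cli/angioquant.R`.

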