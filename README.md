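# retquant

Quantitative retinal biomarkers from en-face OCT/OCTA projection images.

Clinicians and imaging researchers have many candidate biomarkers for
retinal disease — texture of the projection slabs, capillary and
large-vessel morphology, the shape of the foveal avascular zone (FAZ) —
but little machinery to quantify them on a common footing and rank their
importance. retquant turns one eye (six grayscale projections: OCT and
OCTA × FULL / ILM-OPL / OPL-BM, plus four binary masks: capillary,
artery, vein, FAZ) into a canonical vector of **452 named biomarkers**,
and carries a cohort of such vectors through univariate feature
selection, cross-validated disease classification and importance
ranking. Segmentation is out of scope; masks are inputs.

The five feature blocks:

* **177 + 177 LBP texture features** (OCT, OCTA). Each pixel is coded as
  LBP(x_c, y_c) = Σ_p 2^p · s(i_p − i_c), s(x) = 1 iff x > 0, over its
  8-neighbourhood; codes are pooled into the 58 *uniform* patterns (≤ 2
  circular bit transitions) plus one non-uniform bin, giving a 59-bin
  normalised histogram per projection slab.
* **43 + 43 vessel features** (capillary, artery ∪ vein). Seven index
  maps on 20 × 20-pixel windows — VAD, VSD, VPI, VDI = VAD/VSD,
  VCI = VPI²/(4π·VAD), VCP (branch points per skeleton pixel), SP (mean
  |curvature| along skeleton paths) — each summarised by max, mean,
  median, std, skewness and (non-excess) kurtosis, plus the box-counting
  fractal dimension −log N_r / log r.
* **12 FAZ parameters**: area, perimeter, circularity index
  4π·area/perimeter², equivalent diameter 2√(area/π), centroid x/y,
  eccentricity, compactness, flatness, anisotropy index
  perimeter/(π·diameter), convexity, orientation angle.

Seeded synthetic generators (procedural vessel networks, parametric FAZ
blobs, Gaussian-random-field textures, and feature-space cohorts with
planted signal) make the whole pipeline testable with no image download.

## Worked example

```r
library(retquant)

spec <- cohort_spec(n_per_group = c(control = 10, DR = 10),
                    image_size = 128,
                    faz_radius = c(control = 14, DR = 12), seed = 7)
ch  <- synth_cohort(spec)              # 20 eye records
tab <- build_feature_table(ch$records) # 20 x 454 (eye_id + 452 + label)

fv <- assemble(ch$records[[1]])
round(fv[c("capillary_VAD_mean", "capillary_FD", "FAZ_CI", "FAZ_area")], 4)
#> capillary_VAD_mean       capillary_FD             FAZ_CI           FAZ_area
#>             0.2389             1.5528             0.9541             0.0376

sel <- select_features(tab, mode = "two_group")   # Shapiro-Wilk gate, p < 0.05
sum(sel$selected)
#> [1] 344
head(sel[, c("feature", "chosen_test", "p_value")], 3)
#>            feature chosen_test      p_value
#> 1 OCT_OPL-BM_LBP59      t-test 1.599218e-22
#> 2         FAZ_area      t-test 1.466963e-20
#> 3     FAZ_diameter      t-test 3.935702e-20

out <- run_pipeline(tab, task = "2class", seed = 7,
                    grid = list(ntree = 300, mtry = 1))
out$result
#> <cv_result> 2class  acc 1.000  prec 1.000  sens 1.000  F1 1.000
round(out$contribution, 2)
#>   LBP_OCT  LBP_OCTA       FAZ capillary
#>     51.65     44.25      2.36      1.74
```

Reading: the per-eye vector is finite and canonically named; 344 of 452
features separate the two synthetic groups at p < 0.05 (this cohort
plants texture, vessel-density and FAZ differences, so broad selection is
expected); the stratified 75/25 random-forest pipeline classifies the
held-out quarter perfectly on this easy cohort; and the contribution
percentages say how much of the total feature importance each biomarker
family carries — here the texture blocks dominate.

Real cohorts are read from disk with `read_eye_record(root, eye_id)`
(one directory per eye: `OCT_FULL.png`, …, `capillary_mask.png`, …, and a
`labels.csv`); `write_cohort()` writes the same layout. A thin CLI over
these functions ships in `inst/cli/retquant.R`
(`synth` / `extract` / `select` / `classify`).

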