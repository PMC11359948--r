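---
title: "Quantitative retinal biomarkers: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative retinal biomarkers: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retquant)
```

## The problem

En-face OCT and OCTA projections of the macula carry three complementary
kinds of information about retinal disease: the *texture* of the
reflectivity pattern in each projection slab, the *morphology of the
vascular network* (capillaries behave differently from arteries and
veins), and the *shape of the foveal avascular zone* (FAZ). retquant turns
one eye — six grayscale projections (OCT and OCTA, each for the FULL,
ILM-OPL and OPL-BM slabs) plus four binary masks (capillary, artery, vein,
FAZ) — into a canonical vector of 452 named scalar biomarkers, and carries
a cohort of such vectors through univariate feature selection,
cross-validated classification and importance ranking. Segmentation is
deliberately out of scope: masks are inputs.

The five blocks of the vector are fixed: 177 OCT LBP features, 177 OCTA
LBP features, 43 capillary features, 43 large-vessel features
(artery ∪ vein) and 12 FAZ parameters. The canonical name grammar is
`{modality}_{layer}_LBP{k}` for texture,
`{structure}_{index}_{stat}` plus `{structure}_FD` for vessels, and
`FAZ_{parameter}`; `feature_names()` and `feature_types()` are the single
source of truth that every downstream report uses.

## Texture: uniform local binary patterns

Each pixel is encoded against its 8-neighbourhood as
$\mathrm{LBP}(x_c, y_c) = \sum_{p=0}^{7} 2^p\, s(i_p - i_c)$, with
$s(x) = 1$ if $x > 0$ and $0$ otherwise. Three conventions are pinned
because the raw code map depends on them:

* **Ties go to 0** — $s(0) = 0$, a strict comparison. Adding a constant to
  every pixel therefore leaves the code map unchanged, which is the
  invariance that makes LBP histograms robust to global illumination
  shifts (and is asserted in the tests).
* **Neighbour order** — $p = 0$ is the east neighbour and $p$ increases
  counter-clockwise. Any fixed circular order produces the same 59-bin
  histogram (uniformity is invariant under rotation of a consistent
  circular order), but the per-pixel codes are order-dependent, so the
  convention matters for code-level oracle tests.
* **No padding** — the 1-pixel border has no complete neighbourhood and is
  excluded rather than invented by padding.

A raw code takes 256 values, but codes are pooled by *uniformity*: the 58
codes whose circular binary representation has at most two 0↔1 transitions
get one bin each (ascending code order, bins `LBP1`–`LBP58`), and all
non-uniform codes share bin `LBP59`. Histograms are normalised by the
count of valid pixels, so each 59-bin block sums to one; the three slabs of
a modality concatenate to 177 features.

## Vessel morphology: windowed index maps

The mask is tiled into non-overlapping 20 × 20-pixel windows (trailing
partial windows are dropped; 20 px is the conventional local-window size
for 3 × 3 mm OCTA grids and is a tunable argument). The skeleton, the
boundary and the branch points are computed **once on the whole mask** and
then counted per window — windowing must not cut vessels and create
artificial end effects. Per window:

| index | definition | empty-window convention |
|-------|------------|------------------------|
| VAD | vessel pixels / window pixels | 0 |
| VSD | skeleton pixels / window pixels | 0 |
| VPI | vessel pixels 4-adjacent to background / window pixels | 0 |
| VDI | VAD / VSD | 0 if no skeleton |
| VCI | VPI² / (4π · VAD) | 0 if no vessel |
| VCP | branch points / skeleton pixels | 0 if no skeleton |
| SP  | mean \|κ\| along skeleton paths | 0 if no path ≥ 5 px |

The defined-zero conventions keep the 0/0 ratios finite so that the
distribution summaries below are computable over *all* windows, including
vessel-free ones; including the empty windows is what produces the
strongly negative skewness typical of healthy capillary beds, and is the
default.

Skeletonization uses two-subiteration Guo–Hall thinning, implemented in
the package (vectorised over the full matrix per iteration). It was chosen
over the more common Zhang–Suen scheme because it leaves cleaner
junctions: a synthetic "+" crossing thins to exactly one branch pixel
(a skeleton pixel with ≥ 3 skeleton 8-neighbours), which is the definition
VCP counts, and a 5 × 50 bar keeps ≥ 46 of its 50 skeleton pixels (end
erosion bounded by the half-width).

The shape parameter SP discretises the planar curvature
$\kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^{3/2}$: within each window the
skeleton is decomposed into simple arcs by deleting branch pixels, each
arc is walked from an endpoint, its pixel coordinates are smoothed with a
centred 5-point moving average (shrinking at the ends) to suppress
lattice jaggedness, and derivatives are taken by central differences.
Arcs shorter than 5 pixels carry no curvature sample; a straight line
yields exactly 0. Closed loops without endpoints are rare at window scale
and are skipped.

The boundary count for VPI treats out-of-image neighbours as vessel
continuation (replicate padding), so the image frame itself is never
counted as perimeter.

Each of the seven maps is summarised by max, mean, median, sample standard
deviation (n − 1), Fisher–Pearson skewness and **non-excess** Pearson
kurtosis (3 for a normal distribution — the convention is pinned by a
Monte-Carlo test). Skewness and kurtosis of a constant map are defined as
0 rather than NaN so degenerate masks cannot poison a feature table. The
42 summaries plus the box-counting fractal dimension give 43 features per
structure.

**Fractal dimension** counts occupied boxes at dyadic sizes
$r \in \{2, 4, \dots, \le \min(H, W)/4\}$ and reports the least-squares
slope of $\log N(r)$ against $\log(1/r)$. The estimator hits its three
analytic anchors on 256 × 256 grids — a point gives ≈ 0, a straight line
≈ 1, a filled plane ≈ 2 — which the acceptance checks recompute.

## FAZ morphometry

Twelve parameters are measured on the largest 8-connected component of
the FAZ mask (stray pixels must not corrupt the moments): area, perimeter,
circularity index $CI = 4\pi A / P^2$, equivalent-circle diameter
$2\sqrt{A/\pi}$, centroid, and six shape descriptors — eccentricity,
flatness (minor/major axis) and orientation angle of the equivalent
second-moment ellipse, compactness (area / bounding box), anisotropy
index $P / (\pi D)$, and convexity (area / convex area).

Two numerical choices deserve justification:

* **Perimeter estimator.** Counting boundary *pixels* underestimates the
  length of a digital circle by ~12%, which would push the CI of a perfect
  disk to ≈ 1.25 — useless for an index whose defining property is "1 for
  a circle". The perimeter is therefore the traced 8-connected contour
  chain length with Vossepoel–Smeulders step weights (0.980 isothetic,
  1.406 diagonal), accurate to ~1% on disks and exactly invariant under
  90° rotations. A rasterised disk of radius 40 scores CI ≈ 0.93 and
  anisotropy ≈ 1.04.
* **Convexity.** Both numerator and denominator are pixel counts: the
  convex area is the number of pixels whose centres fall inside the convex
  hull of the region's pixel centres. This guarantees convexity ≤ 1 and
  gives ≈ 1 for convex shapes; a polygon-area hull would systematically
  read ≈ 0.975 on a radius-40 disk purely from rasterisation.

CI and the anisotropy index are algebraic inverses,
$CI \cdot a^2 = 1$ — both are computed from the same pixel-unit area and
perimeter, so the identity holds to machine precision and is asserted.
Reported units: area as a fraction of image pixels, perimeter as a
fraction of image width, centroid as fractional coordinates, diameter in
pixels (magnitudes typical of published FAZ tables for 3 × 3 mm scans);
`normalize = FALSE` switches to raw pixels, and the normalisation cannot
affect CI or anisotropy by construction.

The ellipse angle is reported in degrees in [−90, 90), measured from the
image x-axis; an axis-aligned rectangle comes out at exactly 0 or −90.

## Feature selection

Each feature is tested for group differences with a normality gate: every
group is screened by Shapiro–Wilk at 0.05, and the parametric branch
(one-way ANOVA for the four-group comparison, pooled-variance two-sided
t-test for control-vs-disease) is taken only when *all* groups pass — the
conservative reading; otherwise Kruskal–Wallis or the Mann–Whitney U test
is used. Constant features short-circuit to p = 1 with a warning.
Selection keeps raw p < 0.05 by default — no multiple-testing correction,
matching how such biomarker screens are usually run — with
Benjamini–Hochberg available as an option (`adjust = "BH"`). A Welch
t-test is likewise available but off by default.

Whether selection should see the test split is genuinely open in this
kind of pipeline: computing it on the full cohort mimics screen-then-model
practice but leaks, computing it on the training split only is clean. Both
are provided (`selection_scope = "train"` is the default in
`run_pipeline()`).

Calibration is checked by simulation: under the null the selection rate at
α = 0.05 is 0.05 ± 0.02 over 1000 features (two groups of 50), and a
3σ mean shift at n = 50 is detected in ≥ 99% of 200 replicates. A
10,000-permutation oracle agrees with the two-group p-values within
Monte-Carlo error.

## Classification and importance ranking

The model registry covers `random_forest`, `gradient_boosted_trees`
(xgboost), `extra_trees` (ranger with the extratrees split rule) and
`svm` (RBF, e1071); further models can be added as registry entries. Tree
models are left unscaled; the SVM standardises features internally
(z-score fit on the training data only), as margin methods require.

The evaluation design is an outer stratified 75/25 holdout with an inner
stratified 5-fold grid search maximising pooled accuracy (ties broken by
grid order), i.e. hyperparameters never see the test quarter. Per-class
training counts are rounded, so 100 balanced samples split 76/24. After
the winning point is refit, features with normalised importance below
0.001 are dropped and the model is retrained on the survivors; if nothing
falls below the threshold, the original model is kept. The SVM has no
importances, so pruning is a documented no-op there.

Metrics follow the confusion-count definitions: accuracy
$(TP+TN)/n$, precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, F1 the
harmonic mean. The 4-class task reports support-weighted one-vs-rest
averages; with support weighting, weighted recall equals accuracy
*identically* (each class contributes $n_k/n \cdot C_{kk}/n_k$), an
identity the tests assert rather than treat as coincidence. All metrics
are recomputable from the stored confusion counts.

Importance ranking normalises the per-feature importances to sum to one;
per-feature-type contribution percentages are the sums of importances
within each of the five blocks, in percent. With fixed seeds the tree
pipelines are bit-reproducible (single-threaded fits; fold assignment and
fitting draw from seeded generators only).

## Synthetic cohorts

Everything above is testable without any download because the package
ships seeded generators at two levels.

**Image level** (`synth_cohort()`): procedural vessel networks (correlated
random-walk strokes of width 1–4 px, Poisson-branching children, stamped
until a target density is reached within ±20%; a non-branching mode draws
disjoint smooth paths whose skeleton provably has no branch points),
parametric FAZ blobs (rasterised ellipses with a band-limited Fourier
perturbation of the boundary — noise raises the anisotropy index
monotonically on average), and Gaussian-random-field textures whose
autocorrelation length is the group knob (LBP histograms respond to local
autocorrelation). OCTA projections overlay the vessel masks on the
texture so their histograms carry a vascular signal; the FAZ is carved out
of the capillary mask. Default study conditions: 304-px grids, capillary
density 0.22 in controls with mild disease rarefaction (0.17–0.19),
combined large-vessel density 0.10, FAZ equivalent radius 28 px in
controls versus 23–24 px in disease with higher eccentricity
(0.47 → 0.55) and more boundary noise — magnitudes chosen once to sit in
the range reported for 3 × 3 mm scans of healthy and diseased maculae.
Every generator is a pure function of (seed, parameters): same seed, same
mask, bit for bit.

**Feature level** (`synth_signal_table()`): a 452-column table of unit
Gaussian noise with a mean shift injected into *named* signal features of
the non-control groups. Image-space generators cannot place a shift into
one designated feature, so recovery experiments — do selection, ranking
and pruning find exactly the planted biomarkers? — run at this level. The
shipped recovery study plants a 3σ shift in 20 random features over two
groups of 30 and, across 10 seeds, requires all 20 to be selected, ≥ 80%
of the importance top-20 to be planted features, and pruning at 0.001 to
keep every planted feature.

What passing these tests does **not** show: the generators make no claim
to OCT speckle statistics, perfusion physics, or disease-specific lesion
morphology. They demonstrate that the measurement chain is correct and
that the statistical machinery recovers known signal under controlled
conditions — conclusions about real cohorts still require real data read
through `read_eye_record()`.

## Problem sizes and runtime choices

The test suite runs image-level checks on 96–160 px grids and 6–20 eye
cohorts, the calibration simulations at 400–1000 features, and the
recovery study at 10 seeds × 60 eyes in feature space; the acceptance
script re-runs the same battery at the sizes quoted above in well under a
minute on one core. These sizes are the package's own choice of a
desk-scale experiment: large enough that every code path (windowing,
skeleton junctions, normality gates, pruning) is genuinely exercised,
small enough to iterate on.

## Known limitations

* Only PNG rasters are read; masks are binarised at "any nonzero pixel".
* The FAZ perimeter estimator is calibrated for smooth regions; for
  fractal-like boundaries the chain-length weights are biased like any
  local estimator.
* SP depends on the path decomposition at branch pixels; dense skeleton
  tangles inside a window can fragment into many short arcs that carry no
  curvature sample.
* The univariate screen tests features independently; correlated features
  (neighbouring LBP bins, summaries of the same map) are selected or
  rejected together and the false-selection count on real data will be
  correlated, not binomial.
* The 4-class task needs ≥ 4 eyes per class for splitting and ≥ 5 per
  class in training for the inner folds; degenerate folds raise an error
  advising a larger cohort rather than silently collapsing classes.
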