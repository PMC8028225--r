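---
title: "Cross-organ radiomics: feature panel, selection, and transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-organ radiomics: feature panel, selection, and transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtx)
```

## The scientific question

A radiomics signature is a set of quantitative image features, selected on
one patient cohort, that stratifies survival. A signature trained on one
organ (say, lung tumors on CT) often fails to transfer to tumors in other
organs, because both the background tissue statistics and the biological
mechanism linking image phenotype to outcome differ. `radtx` implements the
full chain needed to study this: a 143-feature extraction panel, a
test-retest stability filter, repeated Cox-LASSO selection, a median-split
radiomics score with Kaplan-Meier / log-rank evaluation, whole-organ
intensity profiling, and a phantom simulator so the entire experiment runs
without external imaging data.

## The feature panel

`feature_catalog()` fixes the names and order of the 143 features:

* **19 histogram features** — first-order statistics of the in-mask
  intensities (mean, population SD, skewness, kurtosis, percentiles,
  256-bin entropy/uniformity, and so on). Percentiles use the standard
  linear-interpolation rule (type 7).
* **11 shape features** — 8 three-dimensional (voxel-count volume, mesh
  surface area, sphericity, maximum 3D diameter, surface-to-volume ratio,
  compactness 1/2, spherical disproportion) and 3 two-dimensional on the
  largest-area axial slice (roundness factor, eccentricity, solidity).
* **3 fractal features** — box-counting dimension of the mask,
  blanket-method fractal signature dissimilarity of the center slice, and
  gliding-box lacunarity at box size 3.
* **18 sigmoid margin features** — amplitude, center and slope of sigmoid
  fits to intensity profiles along surface normals (±5 mm, 0.5 mm steps),
  each aggregated with mean, median, SD, skewness and the 2.5/97.5
  percentiles.
* **29 texture features** — 11 GLCM statistics at 256 gray levels on the
  whole ROI and on a sub-sampled ROI, 2 GLSZM variabilities at 32 levels,
  and 5 NGTDM features (Amadasun–King, ε = 1e−6) at 256 levels.
* **63 filter features** — 9 first-order statistics of
  Laplacian-of-Gaussian filtered volumes at σ = 0.5–3.5 voxels in 0.5
  steps.

### Numerical choices worth knowing

**Surface meshing.** Sphericity-family features need a surface area, and a
raw voxel surface overestimates the area of a ball by roughly 28% (the
"staircase" effect), pushing sphericity down to ~0.78. `surface_mesh()`
therefore meshes the 0.5 level set of the Gaussian-smoothed (σ = 0.8
voxels) mask indicator by marching tetrahedra with linear edge
interpolation, and sphericity is computed from the *mesh* area and *mesh*
volume of the same closed surface — the isoperimetric inequality then
guarantees sphericity ≤ 1, and digital balls score ≈ 0.99. The `volume`
feature itself stays the exact voxel count times voxel volume.

**Sub-sampled GLCM.** A stride-2 sublattice of the ROI
(`subsample_roi()`) has no voxel pairs at distance 1, so the `_sub` GLCM
features are computed on a stride-2 *decimation* of image and mask placed
on a compact grid (twice the spacing). That preserves the intent —
co-occurrence statistics under coarser spatial sampling of the same ROI —
while keeping the offset geometry at distance 1.

**Margin fits.** Rays are cast along outward surface normals (negative
gradient of a smoothed mask indicator), sampled by trilinear
interpolation, and fit with Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Fits are canonicalized to positive slope; implausible
fits (flat amplitude, center outside the sampled range) are discarded, and
at least 10 converged rays are required.

**Everything texture-related is oracle-tested.** The test suite contains
independent loop-based implementations of the GLCM, GLSZM, NGTDM,
Kaplan-Meier and Cox partial-likelihood computations and requires
agreement to 1e−10 on randomized small grids.

## Stability filter and selection

Test-retest stability is scored with ICC(2,1) — the two-way,
absolute-agreement, single-measurement intraclass correlation — computed
from mean squares; only features with ICC **strictly** above 0.9 pass
(`icc_filter()`). Absolute agreement matters: a feature whose retest values
are systematically offset is penalized even if perfectly rank-correlated.

Selection (`select_features()`) repeats cross-validated Cox-LASSO
(`glmnet`, Breslow ties, 10-fold CV minimizing partial-likelihood
deviance) 20 times; the fold assignment is the only stochastic element.
Features whose nonzero count exceeds 10 of 20 form the final set (the
40-repeat "variant" mode keeps features selected at least 10 of 40 times,
used for the smaller test cohorts). Final coefficients are refit by
unpenalized Cox regression on standardized features.

The radiomics score is the coefficient-weighted sum of z-scored features;
cohorts are median-split (scores ≤ median are low-risk) and compared by
the log-rank test.

## The phantom generator

`make_tumor_phantom()` builds an ellipsoidal tumor in a configurable
background: the mask is the ellipsoid, the image blends core and
background intensity through a sigmoid of the first-order signed distance
(the `margin_slope` parameter is the transition width in mm, so the
recoverable sigmoid slope is its reciprocal), and interior texture is a
Gaussian random field with configurable correlation length and SD.
`make_organ_background()` provides lung (bimodal air/tissue CT mixture),
kidney (unimodal soft-tissue CT) and brain (MR-like) surroundings.
`simulate_survival()` draws exponential event times whose log-hazard is a
linear function of chosen (z-scored) features, plus independent
exponential censoring.

These phantoms are deliberately simple: they have one lesion per volume,
stationary texture, and exactly sigmoidal margins. They are ground-truth
generators for validating the estimators — not realistic tumors — and
their default parameters are the package's study conditions.

## The transfer experiment

`default_experiment_config()` describes one training lung cohort (n = 100)
and three test cohorts (lung / kidney / brain, n = 40 each) on 36³ grids.
Training and test-lung survival is planted on tumor size and margin
sharpness; kidney and brain outcomes are driven by disjoint texture
features. The expected result, confirmed by `run_transfer_replicates()`
over repeated outcome draws, is that the trained score stratifies the
same-organ test cohort and fails on the other two.

Two design decisions are worth making explicit because reasonable
alternatives exist:

* **Frozen versus refit coefficients.** By default the *frozen* training
  score — training standardization and coefficients — is applied to each
  test cohort (`transfer_experiment(refit = FALSE)`): this is the honest
  out-of-sample question "does the trained score stratify this cohort?".
  The generous alternative (`refit = TRUE`) re-standardizes and refits the
  coefficients on the test cohort before stratifying it; because that
  fits and evaluates on the same subjects, it inflates apparent
  significance (a handful of features refit in-sample on n = 40 will
  "stratify" almost any outcome) and is kept only as an explicit option.
* **Exclusion variant.** The experiment is also run with a configurable
  exclusion list (by default the 2.5-percentile histogram feature, an
  organ-background-sensitive feature) removed from the score.

```{r, eval = FALSE}
cfg <- default_experiment_config(seed = 1)
res <- run_experiment(cfg, out_dir = "experiment_out")
res$results          # per-cohort log-rank rows, full and excluded scores
res$report           # per-cohort selected features with repetition counts
autoplot(res$selection)
```

## Problem sizes and runtime

Feature extraction takes roughly a second per 36³ phantom (dominated by
the seven FFT-based LoG convolutions and 150 sigmoid ray fits). The full
default experiment — 220 phantoms, feature extraction, ICC filtering, and
repeated selection — runs in minutes on one CPU. Cohort sizes, grid shape,
ray counts and selection parameters are all configuration entries and were
chosen so that the complete analysis, including repeated transfer
replicates, stays comfortably within an interactive budget.
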