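# radtx

Cross-organ radiomics: feature extraction, test-retest stability
filtering, survival-driven feature selection, risk stratification, and
whole-organ intensity profiling — plus a tumor-phantom simulator so the
entire analysis runs end to end without external imaging data.

## The scientific problem

Radiomics signatures — panels of quantitative features computed from a
tumor's image and segmentation — can stratify patient survival, but a
signature trained on one organ often fails to transfer to tumors in other
organs: the surrounding tissue statistics change, and so does the
biological mechanism linking image phenotype to outcome. `radtx` provides
the full pipeline needed to study this question quantitatively:

1. a fixed **143-feature panel**: 19 histogram, 11 shape (3D + 2D),
   3 fractal, 18 sigmoid tumor-margin, 29 texture (GLCM / GLSZM / NGTDM)
   and 63 Laplacian-of-Gaussian filter features
   (`feature_catalog()`, `extract_features()`);
2. a **test-retest stability filter** using ICC(2,1) with a strict 0.9
   threshold (`icc_filter()`);
3. **repeated cross-validated Cox-LASSO** selection (20 repeats, features
   kept when selected more than 10 times), refit by unpenalized Cox
   regression (`select_features()`);
4. a **radiomics score** with median-split risk groups, Kaplan-Meier
   curves and log-rank testing (`radiomics_score()`, `stratify_cohort()`);
5. **whole-organ intensity histograms** with z-score normalization for
   cross-modality comparison (`organ_histogram()`, `znormalize_histogram()`);
6. a **phantom and survival simulator** with known ground truth
   (`make_tumor_phantom()`, `simulate_survival()`), and an orchestrated
   cross-organ transfer experiment (`run_experiment()`).

Everything is tidyverse-native: tabular inputs and outputs are tibbles,
fitted objects support `tidy()` / `glance()`, and result types have
`autoplot()` methods.

## Worked example

Simulate a phantom with known geometry and margin, and extract features:

```r
library(radtx)

ph <- make_tumor_phantom(semi_axes = c(11, 9, 9), margin_slope = 1.5,
                         texture_sd = 30, seed = 42)
fv <- extract_features(ph$volume, ph$mask)
fv[, c("hist_mean", "shape3d_volume", "shape3d_sphericity",
       "shape3d_max_3d_diameter", "sigmoid_slope_mean",
       "glcm_contrast_whole", "fractal_box_dimension")]
#>   hist_mean shape3d_volume shape3d_sphericity shape3d_max_3d_diameter
#> 1 -160.6131           3800             0.9806                 21.6102
#>   sigmoid_slope_mean glcm_contrast_whole fractal_box_dimension
#> 1             0.6458            1162.499                2.3255
```

The ground truth is recovered: the 11×9×9 mm ellipsoid has volume
3800 mm³ (4/3·π·11·9·9 ≈ 3731), near-unit sphericity, a maximum diameter
≈ 2×11 mm, and the fitted margin slope 0.6458 ≈ 1/1.5, the reciprocal of
the generative margin width.

Select survival-related features and stratify:

```r
fx <- simulate_feature_table(300, paste0("f", 1:10), seed = 7)
co <- simulate_survival(fx, beta = c(f1 = 1.5, f2 = -1.5),
                        baseline_rate = 0.02, censor_rate = 0.005, seed = 8)
sel <- select_features(co, n_repeats = 20, count_threshold = 10,
                       cv_folds = 10, seed = 9)
sel
#> <rad_selection> 20 repeats, rule: count > 10
#>   10 candidate features -> 3 selected
#> # A tibble: 3 × 3
#>   feature count selected
#>   <chr>   <int> <lgl>
#> 1 f1         20 TRUE
#> 2 f2         20 TRUE
#> 3 f6         20 TRUE

stratify_cohort(co, build_score_model(sel))
#> # A tibble: 1 × 6
#>       n n_events cutoff statistic  p_value degenerate
#>   <int>    <int>  <dbl>     <dbl>    <dbl> <lgl>
#> 1   300      217 0.0507      191. 1.72e-43 FALSE
```

Both planted features are selected in 20 of 20 repeats, and the
median-split score separates the risk groups (log-rank p ≈ 2e-43).

Run the full cross-organ transfer experiment (one training lung cohort,
three test cohorts; writes feature tables, selection JSON, results JSON
and a per-cohort report under `out/`):

```r
res <- run_experiment(default_experiment_config(seed = 1), out_dir = "out")
res$results
```

A thin command-line front end is installed with the package
(`system.file("cli", "radtx", package = "radtx")`) with subcommands
`extract`, `phantom`, `select`, `score`, `organ-profile` and `run`.

## Documentation

See the vignette source in `vignettes/radiomics-transfer.Rmd` for the
methods: the feature definitions and numerical conventions (marching-
tetrahedra surface meshing, sub-sampled GLCM decimation, ICC(2,1),
Breslow ties), the phantom generator and its limitations, and the design
of the transfer experiment.
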