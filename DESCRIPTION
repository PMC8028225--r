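Package: radtx
Title: Cross-Organ Radiomics Feature Extraction, Stability Selection and
    Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Extracts a 143-feature radiomics panel (histogram, 3D/2D shape,
    fractal, sigmoid tumor-margin, GLCM/GLSZM/NGTDM texture, and Laplacian-of-
    Gaussian filter features) from 3D image volumes with binary regions of
    interest, filters features by test-retest intraclass correlation, selects
    survival-related features by repeated cross-validated Cox-LASSO, builds a
    radiomics score with median-split risk stratification (Kaplan-Meier,
    log-rank), and profiles whole-organ intensity histograms with z-score
    normalization. Ships a tumor-phantom and survival-cohort simulator so the
    full cross-organ transfer experiment can be run without external imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
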