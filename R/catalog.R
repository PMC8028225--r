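#' The 143-feature catalog
#'
#' Fixed, documented ordering of the full feature panel: 19 histogram,
#' 8 three-dimensional shape, 3 two-dimensional shape, 3 fractal, 18 sigmoid
#' tumor-margin, 29 texture (11 GLCM statistics on the whole ROI, the same 11
#' on a stride-2 sub-sampled ROI, 2 GLSZM, 5 NGTDM) and 63 filter features
#' (7 Laplacian-of-Gaussian scales x 9 first-order statistics). Feature
#' tables produced by [extract_features()] use exactly this column order.
#'
#' @return A tibble with columns `name` and `category`
#'   (`histogram`, `shape3d`, `shape2d`, `fractal`, `sigmoid`, `texture`,
#'   `filter`).
#' @export
feature_catalog <- function() {
  hist_names <- paste0("hist_", c(
    "min", "max", "mean", "median", "sd", "variance", "skewness", "kurtosis",
    "p2.5", "p25", "p75", "p97.5", "iqr", "range", "energy", "entropy",
    "uniformity", "mad", "rms"))
  shape3d_names <- paste0("shape3d_", c(
    "volume", "surface_area", "sphericity", "max_3d_diameter",
    "surface_to_volume_ratio", "compactness1", "compactness2",
    "spherical_disproportion"))
  shape2d_names <- paste0("shape2d_", c("roundness_factor", "eccentricity",
                                        "solidity"))
  fractal_names <- paste0("fractal_", c("box_dimension", "fsd", "lacunarity"))
  sig_stats <- c("mean", "median", "sd", "skewness", "p2.5", "p97.5")
  sigmoid_names <- as.vector(t(outer(c("amplitude", "center", "slope"),
                                     sig_stats, paste, sep = "_")))
  sigmoid_names <- paste0("sigmoid_", sigmoid_names)
  glcm_stats <- c("energy", "entropy", "contrast", "homogeneity",
                  "dissimilarity", "correlation", "imc1",
                  "sum_of_squares_variance", "sum_average", "sum_entropy",
                  "difference_entropy")
  glcm_names <- c(paste0("glcm_", glcm_stats, "_whole"),
                  paste0("glcm_", glcm_stats, "_sub"))
  glszm_names <- paste0("glszm_", c("size_zone_variability",
                                    "intensity_variability"))
  ngtdm_names <- paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                    "complexity", "strength"))
  log_stats <- c("mean", "sd", "skewness", "kurtosis", "median", "p2.5",
                 "p97.5", "entropy", "uniformity")
  sigmas <- log_sigmas()
  log_names <- as.vector(t(outer(sprintf("log_sigma%.1f", sigmas), log_stats,
                                 paste, sep = "_")))
  tibble::tibble(
    name = c(hist_names, shape3d_names, shape2d_names, fractal_names,
             sigmoid_names, glcm_names, glszm_names, ngtdm_names, log_names),
    category = c(rep("histogram", 19), rep("shape3d", 8), rep("shape2d", 3),
                 rep("fractal", 3), rep("sigmoid", 18),
                 rep("texture", 22), rep("texture", 2), rep("texture", 5),
                 rep("filter", 63)))
}

# LoG scales: sigma in voxels, 0.5 increments over 0.5..3.5.
log_sigmas <- function() seq(0.5, 3.5, by = 0.5)
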