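#' Extract the full 143-feature panel from one volume/mask pair
#'
#' Runs all extractors — histogram, 3D/2D shape, fractal (box-counting
#' dimension, blanket fractal signature dissimilarity, gliding-box
#' lacunarity), sigmoid tumor-margin, GLCM/GLSZM/NGTDM texture, and the
#' Laplacian-of-Gaussian filter bank — and assembles the values in the fixed
#' [feature_catalog()] order. Extraction fails if any feature is missing or
#' non-finite.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask] with at least one foreground voxel.
#' @param n_rays Boundary rays for the sigmoid margin fits.
#' @return A one-row tibble with 143 feature columns.
#' @export
extract_features <- function(img, mask, n_rays = 150L) {
  check_pair(img, mask)
  vals <- c(
    histogram_features(img, mask),
    shape3d_features(mask, img$spacing),
    shape2d_features(mask, img$spacing),
    fractal_box_dimension = box_counting_dimension(mask),
    fractal_fsd = blanket_fsd(img, mask),
    fractal_lacunarity = lacunarity(mask),
    sigmoid_margin_features(img, mask, n_rays = n_rays),
    texture_features(img, mask),
    log_filter_features(img, mask))
  cat_names <- feature_catalog()$name
  missing <- setdiff(cat_names, names(vals))
  if (length(missing)) {
    stop("missing features at assembly: ", paste(missing, collapse = ", "))
  }
  vals <- vals[cat_names]
  if (!all(is.finite(vals))) {
    stop("non-finite feature values: ",
         paste(cat_names[!is.finite(vals)], collapse = ", "))
  }
  tibble::as_tibble(as.list(vals))
}

#' Extract features for a cohort of volume/mask pairs
#'
#' @param volumes List of [rad_volume] objects.
#' @param masks List of [rad_mask] objects, parallel to `volumes`.
#' @param subject_ids Character vector of subject identifiers.
#' @param n_rays Boundary rays for the sigmoid margin fits.
#' @return A tibble with `subject_id` followed by the 143 feature columns.
#' @export
extract_cohort <- function(volumes, masks, subject_ids = NULL,
                           n_rays = 150L) {
  stopifnot(length(volumes) == length(masks))
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%03d", seq_along(volumes))
  }
  rows <- purrr::map2(volumes, masks, extract_features, n_rays = n_rays)
  dplyr::bind_cols(tibble::tibble(subject_id = subject_ids),
                   dplyr::bind_rows(rows))
}

#' Write a feature table to CSV
#'
#' One row per subject, `subject_id` first, then the 143 features in catalog
#' order. Numeric values survive a write/read round trip exactly (shortest
#' round-trip decimal representation).
#'
#' @param features A tibble from [extract_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cat_names <- feature_catalog()$name
  missing <- setdiff(cat_names, names(features))
  if (length(missing)) {
    stop("feature table is missing catalog features: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  features <- dplyr::select(features, "subject_id",
                            dplyr::all_of(cat_names))
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return A tibble with `subject_id` and the catalog feature columns.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(subject_id = readr::col_character(),
                                          .default = readr::col_double()))
}
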