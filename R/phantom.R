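# Synthetic phantoms: organ backgrounds, textured ellipsoidal tumors with
# sigmoid-blurred margins, test-retest pairs, and survival simulation.
# These generators define the study conditions for every downstream stage.

#' Synthetic whole-organ background volume
#'
#' Emulates organ-level intensity distributions: lung CT as a two-component
#' mixture (dominant air-like mode near -850 HU, minor soft-tissue mode near
#' +40 HU), kidney CT as a unimodal soft-tissue distribution near +30 HU
#' (SD 20 HU), and brain MR as a unimodal arbitrary-unit distribution
#' (mean 500, SD 100). The organ mask is a centered ellipsoid covering the
#' simulated parenchyma; CT voxels outside it sit at air (-1000 HU), MR
#' voxels at 0.
#'
#' @param organ One of `"lung"`, `"kidney"`, `"brain"`.
#' @param shape Grid shape (each axis >= 32).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list with `volume` ([rad_volume]) and `mask` ([rad_mask]).
#' @export
make_organ_background <- function(organ, shape = c(48, 48, 48),
                                  spacing = c(1, 1, 1), seed = 1L) {
  organ <- match.arg(organ, c("lung", "kidney", "brain"))
  stopifnot(all(shape >= 32))
  set.seed(seed)
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - (shape[i] + 1) / 2)) /
                 (0.42 * shape[i]))
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  m <- rho2 <= 1
  n_in <- sum(m)
  vol <- if (organ == "lung") {
    bg <- array(-1000, shape)
    comp <- stats::runif(n_in) < 0.8
    v <- ifelse(comp, stats::rnorm(n_in, -850, 60), stats::rnorm(n_in, 40, 25))
    bg[m] <- v
    rad_volume(bg, spacing, "CT")
  } else if (organ == "kidney") {
    bg <- array(-1000, shape)
    bg[m] <- stats::rnorm(n_in, 30, 20)
    rad_volume(bg, spacing, "CT")
  } else {
    bg <- array(0, shape)
    bg[m] <- stats::rnorm(n_in, 500, 100)
    rad_volume(bg, spacing, "MR")
  }
  list(volume = vol, mask = rad_mask(m))
}

#' Textured ellipsoidal tumor phantom
#'
#' The mask is the discretized ellipsoid with the given semi-axes (mm). The
#' image is `background + (core - background) * s(-d / margin_slope)`, where
#' `d` is the (first-order) signed distance to the ellipsoid surface in mm
#' and `s` the logistic function, plus a zero-mean Gaussian random field
#' (white noise smoothed to correlation length `texture_corr_len` mm and
#' rescaled to SD `texture_sd`) inside the mask. `margin_slope = 0` gives a
#' hard step edge.
#'
#' @param semi_axes Ellipsoid semi-axes `(a, b, c)` in mm.
#' @param texture_corr_len Correlation length of the interior texture, mm.
#' @param texture_sd SD of the interior texture, intensity units.
#' @param margin_slope Width of the sigmoid margin transition, mm (>= 0).
#' @param core_intensity Interior intensity.
#' @param background_intensity Background intensity.
#' @param grid_shape Grid shape in voxels.
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @return A list with `volume` ([rad_volume]) and `mask` ([rad_mask]).
#' @export
make_tumor_phantom <- function(semi_axes = c(10, 10, 10),
                               texture_corr_len = 2, texture_sd = 20,
                               margin_slope = 1, core_intensity = 40,
                               background_intensity = -850,
                               grid_shape = c(40, 40, 40),
                               spacing = c(1, 1, 1), seed = 1L) {
  stopifnot(all(semi_axes > 0), margin_slope >= 0)
  extent_vox <- semi_axes / spacing
  if (any(extent_vox + 2 > (grid_shape - 1) / 2)) {
    stop("phantom exceeds grid (needs >= 2-voxel clearance)")
  }
  set.seed(seed)
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(i) (seq_len(grid_shape[i]) - ctr[i]) * spacing[i])
  # rho and |grad rho| for the first-order signed distance d = (rho-1)/|grad rho|
  x2 <- outer(outer((ax[[1]] / semi_axes[1])^2, (ax[[2]] / semi_axes[2])^2,
                    "+"), (ax[[3]] / semi_axes[3])^2, "+")
  rho <- sqrt(x2)
  g2 <- outer(outer((ax[[1]] / semi_axes[1]^2)^2,
                    (ax[[2]] / semi_axes[2]^2)^2, "+"),
              (ax[[3]] / semi_axes[3]^2)^2, "+")
  grad_rho <- sqrt(g2) / pmax(rho, 1e-9)
  d <- (rho - 1) / pmax(grad_rho, 1e-9)
  d[rho < 1e-9] <- -min(semi_axes)
  m <- rho <= 1
  w <- if (margin_slope > 0) 1 / (1 + exp(d / margin_slope)) else
    (d <= 0) * 1  # step profile; arithmetic keeps the array dims
  img <- background_intensity + (core_intensity - background_intensity) * w
  if (texture_sd > 0) {
    noise <- array(stats::rnorm(prod(grid_shape)), grid_shape)
    for (axn in 1:3) {
      s_vox <- texture_corr_len / spacing[axn]
      if (s_vox > 0) {
        r <- max(1L, ceiling(3 * s_vox))
        k <- exp(-((-r):r)^2 / (2 * s_vox^2)); k <- k / sum(k)
        noise <- convolve_axis(noise, k, r, axn)
      }
    }
    s_in <- stats::sd(noise[m])
    if (s_in > 0) img <- img + (noise * (texture_sd / s_in)) * m
  }
  list(volume = rad_volume(img, spacing, "SYNTH"), mask = rad_mask(m))
}

#' Simulated test-retest scan pair
#'
#' The second scan is the first plus i.i.d. Gaussian noise and an
#' integer-voxel rigid shift (up to `jitter_vox` per axis, circular so the
#' mask voxel count is preserved) applied to both image and mask.
#'
#' @param volume A [rad_volume].
#' @param mask A [rad_mask].
#' @param noise_sd SD of the added noise (>= 0).
#' @param jitter_vox Maximum integer shift per axis (>= 0).
#' @param seed Integer seed.
#' @return A list with `test` and `retest`, each a list of `volume`, `mask`.
#' @export
make_retest_pair <- function(volume, mask, noise_sd = 0, jitter_vox = 0L,
                             seed = 1L) {
  stopifnot(noise_sd >= 0, jitter_vox >= 0)
  set.seed(seed)
  shift <- if (jitter_vox > 0) {
    sample(seq(-jitter_vox, jitter_vox), 3, replace = TRUE)
  } else c(0L, 0L, 0L)
  img2 <- shift_array(volume$data, shift)
  m2 <- shift_array(mask$data, shift)
  if (noise_sd > 0) {
    img2 <- img2 + array(stats::rnorm(length(img2), 0, noise_sd), dim(img2))
  }
  list(test = list(volume = volume, mask = mask),
       retest = list(volume = rad_volume(img2, volume$spacing,
                                         volume$modality),
                     mask = rad_mask(m2)))
}

#' Simulate survival outcomes from planted feature effects
#'
#' Event times are exponential with subject rate
#' `baseline_rate * exp(sum(beta * z))`, where `z` are the per-cohort
#' standardized values of the features named in `beta`; censoring times are
#' exponential with rate `censor_rate` (no censoring when 0), independent of
#' the covariates. `time = min(T, C)`, `event = 1{T <= C}`.
#'
#' @param features Tibble with `subject_id` and feature columns.
#' @param beta Named numeric vector of log-hazard coefficients; every name
#'   must be a feature column.
#' @param baseline_rate Baseline hazard rate (> 0), 1/time units.
#' @param censor_rate Censoring hazard rate (>= 0).
#' @param seed Integer seed.
#' @return The input tibble with `time` and `event` columns added.
#' @export
simulate_survival <- function(features, beta = numeric(0),
                              baseline_rate = 0.01, censor_rate = 0,
                              seed = 1L) {
  stopifnot(baseline_rate > 0, censor_rate >= 0)
  unknown <- setdiff(names(beta), names(features))
  if (length(unknown)) {
    stop("unknown feature name in beta: ", paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  n <- nrow(features)
  lp <- rep(0, n)
  if (length(beta)) {
    z <- scale(as.matrix(features[names(beta)]))
    z[!is.finite(z)] <- 0  # constant feature contributes nothing
    lp <- as.vector(z %*% beta)
  }
  t_event <- stats::rexp(n, baseline_rate * exp(lp))
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  dplyr::mutate(features, time = pmin(t_event, t_cens),
                event = as.integer(t_event <= t_cens))
}

#' Simulate a plain feature table of independent standard normal features
#'
#' Used for selection-recovery experiments where the features themselves
#' need no imaging provenance.
#'
#' @param n Number of subjects.
#' @param feature_names Character vector of feature column names.
#' @param seed Integer seed.
#' @return A tibble with `subject_id` and the feature columns.
#' @export
simulate_feature_table <- function(n, feature_names, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * length(feature_names)), n,
              dimnames = list(NULL, feature_names))
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))),
                   tibble::as_tibble(m))
}

#' Simulate a test-retest pair of feature tables
#'
#' The retest table equals the test table plus Gaussian measurement noise of
#' SD `noise_frac` times each feature's SD; features listed in `unstable`
#' are instead redrawn independently (zero test-retest agreement).
#'
#' @param features Tibble with `subject_id` and feature columns.
#' @param noise_frac Relative measurement noise for stable features.
#' @param unstable Character vector of feature names to destabilize.
#' @param seed Integer seed.
#' @return A list of tibbles `test` and `retest`.
#' @export
simulate_retest_tables <- function(features, noise_frac = 0.05,
                                   unstable = character(0), seed = 1L) {
  set.seed(seed)
  fcols <- setdiff(names(features), "subject_id")
  retest <- features
  for (f in fcols) {
    v <- features[[f]]
    s <- stats::sd(v)
    retest[[f]] <- if (f %in% unstable) {
      stats::rnorm(length(v), mean(v), if (s > 0) s else 1)
    } else {
      v + stats::rnorm(length(v), 0, noise_frac * s)
    }
  }
  list(test = features, retest = retest)
}

#' Simulate a cohort of tumor phantoms and extract their features
#'
#' Per-subject phantom parameters are drawn from fixed realistic ranges
#' (semi-axes 6-13 mm, margin width 0.5-3 mm, texture SD 10-60, correlation
#' length 1-4 mm) on the requested organ background intensity pair, the
#' phantom is generated, and the full 143-feature panel is extracted.
#'
#' @param n Number of subjects.
#' @param organ `"lung"`, `"kidney"` or `"brain"` (sets core/background
#'   intensities).
#' @param grid_shape Phantom grid (default 36^3).
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed.
#' @param n_rays Boundary rays for the sigmoid margin features.
#' @return A list with `features` (tibble), `params` (tibble of generating
#'   parameters) and, for reuse, the last `volume`/`mask` pair.
#' @export
simulate_tumor_cohort <- function(n, organ = "lung",
                                  grid_shape = c(36, 36, 36),
                                  spacing = c(1, 1, 1), seed = 1L,
                                  n_rays = 150L) {
  organ <- match.arg(organ, c("lung", "kidney", "brain"))
  levels <- switch(organ,
    lung = c(core = 40, bg = -850),
    kidney = c(core = 80, bg = 30),
    brain = c(core = 650, bg = 500))
  set.seed(seed)
  max_ax <- (min(grid_shape) - 1) / 2 - 2.5
  par_tbl <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    a = stats::runif(n, 6, min(13, max_ax)),
    b = stats::runif(n, 6, min(13, max_ax)),
    c = stats::runif(n, 6, min(13, max_ax)),
    margin_slope = stats::runif(n, 0.5, 3),
    texture_sd = stats::runif(n, 10, 60),
    texture_corr_len = stats::runif(n, 1, 4),
    phantom_seed = sample.int(1e6, n))
  rows <- vector("list", n)
  last <- NULL
  for (i in seq_len(n)) {
    ph <- make_tumor_phantom(
      semi_axes = c(par_tbl$a[i], par_tbl$b[i], par_tbl$c[i]),
      texture_corr_len = par_tbl$texture_corr_len[i],
      texture_sd = par_tbl$texture_sd[i],
      margin_slope = par_tbl$margin_slope[i],
      core_intensity = levels[["core"]],
      background_intensity = levels[["bg"]],
      grid_shape = grid_shape, spacing = spacing,
      seed = par_tbl$phantom_seed[i])
    rows[[i]] <- extract_features(ph$volume, ph$mask, n_rays = n_rays)
    last <- ph
  }
  feats <- dplyr::bind_cols(
    tibble::tibble(subject_id = par_tbl$subject_id),
    dplyr::bind_rows(rows))
  list(features = feats, params = par_tbl, volume = last$volume,
       mask = last$mask)
}
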