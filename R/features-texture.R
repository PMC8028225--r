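# Texture features: GLCM (256 levels, whole + sub-sampled ROI),
# GLSZM (32 levels), NGTDM (256 levels).

#' Quantize in-mask intensities to equal-width gray levels
#'
#' Equal-width bins over the in-mask intensity range; the in-mask maximum
#' maps to level `n_levels`. A constant ROI maps entirely to level 1.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask].
#' @param n_levels Number of gray levels (>= 2).
#' @return A list with `grid` (integer array, levels 1..N inside the mask,
#'   0 outside), `mask` (logical array) and `n_levels`.
#' @export
quantize <- function(img, mask, n_levels) {
  check_pair(img, mask)
  stopifnot(n_levels >= 2)
  m <- mask$data
  x <- img$data[m]
  rng <- range(x)
  g <- array(0L, dim(img$data))
  if (rng[1] == rng[2]) {
    g[m] <- 1L
  } else {
    lev <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L,
                as.integer(n_levels))
    g[m] <- lev
  }
  list(grid = g, mask = m, n_levels = as.integer(n_levels))
}

# Pooled symmetric GLCM over the 13 unique 3D directions at distance 1
# (index space). Returns the normalized N x N joint probability matrix.
glcm_matrix <- function(q) {
  g <- q$grid; m <- q$mask; N <- q$n_levels
  dirs <- directions_13()
  counts <- numeric(N * N)
  for (k in seq_len(nrow(dirs))) {
    o <- dirs[k, ]
    sg <- shift_valid(g, o)
    sm <- shift_valid(m, o)
    ok <- m & sm
    i <- g[ok]; j <- sg[ok]
    idx <- (j - 1L) * N + i
    tb <- tabulate(idx, N * N)
    counts <- counts + tb
    idx2 <- (i - 1L) * N + j
    counts <- counts + tabulate(idx2, N * N)
  }
  if (sum(counts) == 0) stop("no valid voxel pairs for GLCM")
  matrix(counts / sum(counts), N, N)
}

# The 11 GLCM statistics from a normalized co-occurrence matrix.
glcm_stats_from_matrix <- function(P) {
  N <- nrow(P)
  i <- row(P); j <- col(P)
  pij <- P
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(N) * px); muy <- sum(seq_len(N) * py)
  sx <- sqrt(sum((seq_len(N) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(N) - muy)^2 * py))
  nz <- pij > 0
  entropy <- -sum(pij[nz] * log2(pij[nz]))
  # p_{x+y} and p_{x-y}
  k_sum_t <- tapply(pij, i + j, sum)
  ks <- as.numeric(names(k_sum_t))
  k_sum <- as.vector(k_sum_t)
  k_diff <- as.vector(tapply(pij, abs(i - j), sum))
  corr <- if (sx > 0 && sy > 0) {
    sum((i - mux) * (j - muy) * pij) / (sx * sy)
  } else 1
  hxy1 <- {
    pp <- px[i] * py[j]
    ok <- nz & pp > 0
    -sum(pij[ok] * log2(pp[ok]))
  }
  hx <- shannon_entropy(px); hy <- shannon_entropy(py)
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  c(energy = sum(pij^2),
    entropy = entropy,
    contrast = sum((i - j)^2 * pij),
    homogeneity = sum(pij / (1 + abs(i - j))),
    dissimilarity = sum(abs(i - j) * pij),
    correlation = corr,
    imc1 = imc1,
    sum_of_squares_variance = sum((i - mux)^2 * pij),
    sum_average = sum(ks * k_sum),
    sum_entropy = shannon_entropy(k_sum),
    difference_entropy = shannon_entropy(k_diff))
}

#' GLCM texture features
#'
#' Co-occurrence matrix accumulated over the 13 unique 3D directions at
#' distance 1 voxel, symmetrized, pooled into a single matrix and
#' normalized; 11 statistics are returned. For a degenerate (constant) ROI,
#' correlation is defined as 1 and the information measure of correlation
#' as 0.
#'
#' @param q A quantized ROI from [quantize()] (256 levels by convention).
#' @param suffix Optional suffix appended to feature names (e.g. `"whole"`).
#' @return A named numeric vector of 11 values (`glcm_*`).
#' @export
glcm_features <- function(q, suffix = NULL) {
  st <- glcm_stats_from_matrix(glcm_matrix(q))
  names(st) <- paste0("glcm_", names(st),
                      if (!is.null(suffix)) paste0("_", suffix) else "")
  st
}

#' Sub-sample an ROI to the even-index sublattice
#'
#' Keeps in-mask voxels whose 0-based index is even on every axis (stride 2
#' per axis). If the result is empty the whole mask is returned with a
#' warning.
#'
#' @param mask A [rad_mask].
#' @return A [rad_mask] (subset of the input).
#' @export
subsample_roi <- function(mask) {
  m <- if (inherits(mask, "rad_mask")) mask$data else mask
  d <- dim(m)
  keep <- array(FALSE, d)
  keep[seq(1L, d[1], by = 2L), seq(1L, d[2], by = 2L), seq(1L, d[3], by = 2L)] <- TRUE
  sub <- m & keep
  if (!any(sub)) {
    warning("sub-sampled ROI is empty; falling back to the whole ROI")
    sub <- m
  }
  suppressWarnings(rad_mask(sub))
}

#' GLSZM features
#'
#' Zones are 26-connected components of equal gray level inside the mask
#' (32 levels by convention). With `Z(g, s)` the count of zones of gray
#' level `g` and size `s`, returns size-zone variability
#' `sum_s (sum_g Z)^2 / sum Z` and intensity (gray-level) variability
#' `sum_g (sum_s Z)^2 / sum Z`.
#'
#' @param q A quantized ROI from [quantize()].
#' @return A named numeric vector of 2 values (`glszm_*`).
#' @export
glszm_features <- function(q) {
  lab <- label_components_3d(q$grid, q$mask, connectivity = 26)
  labs <- lab[q$mask]
  sizes <- tabulate(labs)
  lev <- q$grid[q$mask]
  zone_level <- lev[match(seq_along(sizes), labs)]
  nz <- length(sizes)
  size_marg <- table(sizes)              # zones per size
  level_marg <- table(zone_level)        # zones per gray level
  c(glszm_size_zone_variability = sum(as.numeric(size_marg)^2) / nz,
    glszm_intensity_variability = sum(as.numeric(level_marg)^2) / nz)
}

#' NGTDM features
#'
#' Neighborhood gray-tone difference features in the Amadasun-King form,
#' with the 26-neighborhood restricted to in-mask neighbors. `s(i)` sums
#' `|i - mean neighborhood level|` over voxels of level `i`; `p(i)` is the
#' level occupancy. Coarseness uses epsilon = 1e-6 in the denominator, so a
#' constant ROI reports the documented cap 1e6; busyness is 0 when its
#' denominator vanishes.
#'
#' @param q A quantized ROI from [quantize()] (256 levels by convention).
#' @return A named numeric vector of 5 values (`ngtdm_*`).
#' @export
ngtdm_features <- function(q) {
  eps <- 1e-6
  g <- q$grid; m <- q$mask; N <- q$n_levels
  nb_sum <- array(0, dim(g)); nb_n <- array(0L, dim(g))
  offs <- neighbor_offsets_26()
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb_sum <- nb_sum + shift_valid(g * as.numeric(m), o)
    nb_n <- nb_n + shift_valid(m, o)
  }
  has_nb <- m & nb_n > 0
  lev <- g[has_nb]
  abar <- nb_sum[has_nb] / nb_n[has_nb]
  n_tot <- sum(has_nb)
  s_i <- numeric(N); n_i <- numeric(N)
  agg <- tapply(abs(lev - abar), lev, sum)
  s_i[as.integer(names(agg))] <- agg
  cnt <- tabulate(lev, N)
  p_i <- cnt / n_tot
  present <- which(p_i > 0)
  Ng <- length(present)
  ps <- sum(p_i * s_i)
  coarseness <- 1 / (eps + ps)
  contrast <- if (Ng > 1) {
    ii <- present
    pm <- outer(p_i[ii], p_i[ii])
    dm <- outer(ii, ii, "-")^2
    (sum(pm * dm) / (Ng * (Ng - 1))) * (sum(s_i) / n_tot)
  } else 0
  busy_den <- if (Ng > 1) {
    ii <- present
    sum(abs(outer(ii * p_i[ii], ii * p_i[ii], "-")))
  } else 0
  busyness <- if (busy_den > 0) ps / busy_den else 0
  complexity <- if (Ng > 1) {
    ii <- present
    num <- outer(p_i[ii] * s_i[ii], p_i[ii] * s_i[ii], "+")
    den <- outer(p_i[ii], p_i[ii], "+")
    sum(abs(outer(ii, ii, "-")) * num / den) / n_tot
  } else 0
  strength <- if (Ng > 1) {
    ii <- present
    sum(outer(p_i[ii], p_i[ii], "+") * outer(ii, ii, "-")^2) / (eps + sum(s_i))
  } else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' All 29 texture features
#'
#' GLCM statistics on the whole ROI and on the stride-2 sub-sampled ROI
#' (256 levels), GLSZM variabilities (32 levels) and NGTDM features
#' (256 levels).
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask].
#' @return A named numeric vector of 29 values.
#' @export
texture_features <- function(img, mask) {
  check_pair(img, mask)
  q256 <- quantize(img, mask, 256L)
  whole <- glcm_features(q256, "whole")
  subf <- glcm_features(quantize_subsampled(img, mask), "sub")
  q32 <- quantize(img, mask, 32L)
  c(whole, subf, glszm_features(q32), ngtdm_features(q256))
}

# Quantized stride-2 decimation of image and mask: the even-sublattice
# voxels of subsample_roi() arranged on a compact grid so that distance-1
# co-occurrence offsets relate retained voxels. Falls back to the whole ROI
# when the decimated mask is empty.
quantize_subsampled <- function(img, mask, n_levels = 256L) {
  d <- dim(img$data)
  ix <- seq(1L, d[1], by = 2L); iy <- seq(1L, d[2], by = 2L)
  iz <- seq(1L, d[3], by = 2L)
  md <- mask$data[ix, iy, iz, drop = FALSE]
  if (!any(md)) {
    warning("sub-sampled ROI is empty; falling back to the whole ROI")
    return(quantize(img, mask, n_levels))
  }
  vol <- rad_volume(img$data[ix, iy, iz, drop = FALSE],
                    spacing = img$spacing * 2, modality = img$modality)
  quantize(vol, suppressWarnings(rad_mask(md)), n_levels)
}
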