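# First-order (histogram) and shape features.

# Shared first-order statistic battery used by both the in-mask histogram
# features and the per-sigma LoG statistics. Percentiles use linear
# interpolation between order statistics (stats::quantile type 7); SD and
# variance use the population convention (divide by n). Entropy/uniformity
# are computed on a 256-bin equal-width quantization of the value range.
first_order_stats <- function(x, n_bins = 256L) {
  n <- length(x)
  mu <- mean(x)
  v <- if (n >= 2) sum((x - mu)^2) / n else 0
  s <- sqrt(v)
  qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                        type = 7)
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - mu)^4) / s^4 else 0
  rng <- range(x)
  p <- bin_probs(x, n_bins)
  list(min = rng[1], max = rng[2], mean = mu, median = qs[3], sd = s,
       variance = v, skewness = skew, kurtosis = kurt,
       p2.5 = qs[1], p25 = qs[2], p75 = qs[4], p97.5 = qs[5],
       iqr = qs[4] - qs[2], range = rng[2] - rng[1],
       energy = sum(x^2), entropy = shannon_entropy(p),
       uniformity = sum(p^2), mad = mean(abs(x - mu)),
       rms = sqrt(mean(x^2)))
}

bin_probs <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(1)
  b <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  tabulate(b, n_bins)[tabulate(b, n_bins) > 0] / length(x)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Histogram (first-order) features of in-mask intensities
#'
#' 19 first-order statistics of the voxel intensities inside the ROI:
#' min, max, mean, median, population SD and variance, skewness, kurtosis,
#' the 2.5/25/75/97.5 percentiles, IQR, range, energy (sum of squares),
#' entropy and uniformity on a 256-bin equal-width quantization of the
#' in-mask range, mean absolute deviation, and root mean square.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask] with at least one foreground voxel.
#' @return A named numeric vector of 19 values (`hist_*`).
#' @export
histogram_features <- function(img, mask) {
  check_pair(img, mask)
  x <- img$data[mask$data]
  st <- first_order_stats(x)
  out <- unlist(st)
  names(out) <- paste0("hist_", names(st))
  out
}

#' 3D shape features of a mask
#'
#' Volume is the exact voxel count times voxel volume; surface area and the
#' mesh-enclosed volume come from a marching-tetrahedra mesh of the smoothed
#' mask indicator (see [surface_mesh()]). Sphericity, compactness and
#' spherical disproportion are computed from the mesh area and mesh volume of
#' the same closed surface, which bounds sphericity at 1. The maximum 3D
#' diameter is the largest pairwise distance between surface-voxel centers,
#' in mm.
#'
#' @param mask A [rad_mask].
#' @param spacing Voxel spacing in mm.
#' @return A named numeric vector of 8 values (`shape3d_*`).
#' @export
shape3d_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- if (inherits(mask, "rad_mask")) mask$data else mask
  if (!any(m)) stop("mask is empty")
  vox_vol <- prod(spacing)
  volume <- sum(m) * vox_vol
  mesh <- surface_mesh(m, spacing)
  A <- mesh$area
  Vm <- mesh$volume
  sph <- min(1, pi^(1/3) * (6 * Vm)^(2/3) / A)
  r_eq <- (3 * Vm / (4 * pi))^(1/3)
  sv <- surface_voxels(m)
  pts <- voxel_coords_mm(sv, spacing)
  max_d <- max_pairwise_distance(pts)
  c(shape3d_volume = volume,
    shape3d_surface_area = A,
    shape3d_sphericity = sph,
    shape3d_max_3d_diameter = max_d,
    shape3d_surface_to_volume_ratio = A / volume,
    shape3d_compactness1 = Vm / (sqrt(pi) * A^(3/2)),
    shape3d_compactness2 = 36 * pi * Vm^2 / A^3,
    shape3d_spherical_disproportion = A / (4 * pi * r_eq^2))
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(0)
  # prune to points on the axis-aligned extremes' hull candidates when large
  if (n > 2500L) {
    keep <- unique(unlist(lapply(1:3, function(ax) {
      c(which(pts[, ax] == min(pts[, ax])), which(pts[, ax] == max(pts[, ax])))
    })))
    # fall back to full set if pruning is too aggressive for odd shapes
    if (length(keep) < 8L) keep <- seq_len(n)
    # combine extremes with a random-free deterministic thinning
    rest <- setdiff(seq_len(n), keep)
    thin <- rest[seq(1L, length(rest), by = ceiling(length(rest) / 2000))]
    pts <- pts[c(keep, thin), , drop = FALSE]
    n <- nrow(pts)
  }
  sq <- rowSums(pts^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pts)
  sqrt(max(0, max(d2)))
}

#' 2D shape features of the center slice
#'
#' The center slice is the axial (third-axis) slice with the largest in-mask
#' area, ties broken toward the lower index. Features are computed on the
#' largest 8-connected component of that slice: roundness factor
#' `4*pi*A/P^2` (perimeter from the interpolated 0.5 contour of the smoothed
#' indicator), eccentricity of the second-moment ellipse, and solidity
#' (pixel area over convex hull area of pixel corner points). Roundness and
#' solidity are clamped at 1.
#'
#' @param mask A [rad_mask].
#' @param spacing Voxel spacing in mm.
#' @return A named numeric vector of 3 values (`shape2d_*`).
#' @export
shape2d_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- if (inherits(mask, "rad_mask")) mask$data else mask
  if (!any(m)) stop("mask is empty")
  areas <- apply(m, 3, sum)
  zi <- which.max(areas)  # which.max takes the first maximum: lower index
  sl <- m[, , zi]
  if (!any(sl)) stop("center slice is empty")
  lab <- label_slice_8(sl)
  tab <- tabulate(lab[lab > 0])
  sl <- lab == which.max(tab)
  dx <- spacing[1]; dy <- spacing[2]
  A <- sum(sl) * dx * dy
  P <- slice_perimeter(sl, dx, dy)
  rf <- min(1, 4 * pi * A / P^2)
  w <- which(sl, arr.ind = TRUE)
  xy <- cbind((w[, 1] - 1) * dx, (w[, 2] - 1) * dy)
  ecc <- moment_eccentricity(xy)
  sol <- min(1, A / convex_hull_area(xy, dx, dy))
  c(shape2d_roundness_factor = rf, shape2d_eccentricity = ecc,
    shape2d_solidity = sol)
}

# 8-connected labeling of a 2D slice via the 3D labeller on a 1-deep grid.
label_slice_8 <- function(sl) {
  a <- array(sl, c(dim(sl), 1L))
  lab <- label_components_3d(array(1, dim(a)), a, connectivity = 26)
  lab[, , 1]
}

slice_perimeter <- function(sl, dx, dy, sigma = 0.8) {
  d <- dim(sl)
  pmat <- matrix(0, d[1] + 2, d[2] + 2)
  pmat[2:(d[1] + 1), 2:(d[2] + 1)] <- sl
  a <- array(pmat, c(dim(pmat), 1L))
  sm <- gaussian_smooth_3d(a, sigma)[, , 1]
  cl <- grDevices::contourLines(x = seq_len(nrow(sm)) * dx,
                                y = seq_len(ncol(sm)) * dy,
                                z = sm, levels = 0.5)
  if (!length(cl)) return(2 * (dx + dy))  # single-pixel fallback
  sum(vapply(cl, function(s) sum(sqrt(diff(s$x)^2 + diff(s$y)^2)), 0))
}

moment_eccentricity <- function(xy) {
  if (nrow(xy) < 2) return(0)
  cv <- stats::cov(xy)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

convex_hull_area <- function(xy, dx, dy) {
  corners <- rbind(
    sweep(xy, 2, c(-dx, -dy) / 2, "+"), sweep(xy, 2, c(dx, -dy) / 2, "+"),
    sweep(xy, 2, c(-dx, dy) / 2, "+"), sweep(xy, 2, c(dx, dy) / 2, "+"))
  h <- grDevices::chull(corners)
  p <- corners[h, , drop = FALSE]
  n <- nrow(p)
  if (n < 3) return(prod(c(dx, dy)))
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
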