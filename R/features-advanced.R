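# Fractal, sigmoid tumor-margin, and Laplacian-of-Gaussian filter features.

#' Box-counting fractal dimension of a mask
#'
#' Counts occupied boxes at edge lengths 1, 2, 4, 8, 16 voxels, with the box
#' grid anchored at the mask bounding-box corner, and returns the slope of
#' the least-squares fit of `log N(eps)` against `log(1/eps)`.
#'
#' @param mask A [rad_mask].
#' @return Fractal dimension (0 for a single voxel, up to 3 for a filled
#'   volume).
#' @export
box_counting_dimension <- function(mask) {
  m <- if (inherits(mask, "rad_mask")) mask$data else mask
  if (!any(m)) stop("mask is empty")
  w <- which(m, arr.ind = TRUE)
  w <- sweep(w, 2, apply(w, 2, min))  # 0-based within bounding box
  eps <- c(1L, 2L, 4L, 8L, 16L)
  n_boxes <- vapply(eps, function(e) {
    b <- floor(w / e)
    nrow(unique(b))
  }, 0)
  lx <- log(1 / eps)
  ly <- log(n_boxes)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Fractal signature dissimilarity (blanket method)
#'
#' Treats the in-mask intensities of the center slice (largest-area axial
#' slice, ties to the lower index) as a height map and grows upper/lower
#' blankets for scales e = 1..5: `u_e = max(u_{e-1} + 1, 4-neighbor max)`,
#' `l_e = min(l_{e-1} - 1, 4-neighbor min)`, neighbors restricted to the
#' mask. The estimated surface area is `A(e) = sum(u_e - l_e) / (2e)`; the
#' signature is the local log-log slope of `A(e)` between successive scales
#' and the returned dissimilarity is the range (max minus min) of those
#' slopes. A constant image yields 0.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask].
#' @param scales Blanket scales (default 1..5).
#' @return The fractal signature dissimilarity (dimensionless).
#' @export
blanket_fsd <- function(img, mask, scales = 1:5) {
  check_pair(img, mask)
  m <- mask$data
  areas <- apply(m, 3, sum)
  zi <- which.max(areas)
  sl_mask <- m[, , zi]
  if (sum(sl_mask) < 9) stop("center slice too small for the blanket method")
  h <- img$data[, , zi]
  bb <- which(sl_mask, arr.ind = TRUE)
  rx <- range(bb[, 1]); ry <- range(bb[, 2])
  sm <- sl_mask[rx[1]:rx[2], ry[1]:ry[2], drop = FALSE]
  hm <- h[rx[1]:rx[2], ry[1]:ry[2], drop = FALSE]
  if (nrow(sm) < 3 || ncol(sm) < 3) stop("center slice too small for the blanket method")
  u <- l <- hm
  u[!sm] <- -Inf
  l[!sm] <- Inf
  nb_max <- function(a) {
    d <- dim(a)
    pad <- matrix(-Inf, d[1] + 2, d[2] + 2)
    pad[2:(d[1] + 1), 2:(d[2] + 1)] <- a
    pmax(pad[1:d[1], 2:(d[2] + 1)], pad[3:(d[1] + 2), 2:(d[2] + 1)],
         pad[2:(d[1] + 1), 1:d[2]], pad[2:(d[1] + 1), 3:(d[2] + 2)])
  }
  A <- numeric(length(scales))
  for (k in seq_along(scales)) {
    u <- pmax(u + 1, nb_max(u))
    l <- -pmax(-l + 1, nb_max(-l))
    u[!sm] <- -Inf
    l[!sm] <- Inf
    A[k] <- sum(u[sm] - l[sm]) / (2 * scales[k])
  }
  slopes <- diff(log(A)) / diff(log(scales))
  max(slopes) - min(slopes)
}

#' Gliding-box lacunarity of a mask
#'
#' Lacunarity `Lambda(r) = E[M^2] / E[M]^2` of the box mass `M` (foreground
#' count) over all `r^3` boxes fully inside the mask bounding box, at
#' r = 3 voxels. Equals 1 for a fully occupied bounding box and is >= 1
#' always.
#'
#' @param mask A [rad_mask].
#' @param r Box edge length in voxels (default 3).
#' @return Lacunarity at scale `r`.
#' @export
lacunarity <- function(mask, r = 3L) {
  m <- if (inherits(mask, "rad_mask")) mask$data else mask
  if (!any(m)) stop("mask is empty")
  w <- which(m, arr.ind = TRUE)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  bb <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(bb)
  if (any(d < r)) stop("mask bounding box smaller than the gliding box")
  cs <- array(as.numeric(bb), d)
  for (ax in 1:3) cs <- apply_cumsum(cs, ax)
  # box sums via inclusion-exclusion on the padded summed-area table
  S <- array(0, d + 1L)
  S[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cs
  ix <- 1:(d[1] - r + 1); iy <- 1:(d[2] - r + 1); iz <- 1:(d[3] - r + 1)
  g <- function(a, b, c) S[ix + a, iy + b, iz + c, drop = FALSE]
  M <- g(r, r, r) - g(0, r, r) - g(r, 0, r) - g(r, r, 0) +
       g(0, 0, r) + g(0, r, 0) + g(r, 0, 0) - g(0, 0, 0)
  mean(M^2) / mean(M)^2
}

apply_cumsum <- function(a, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  m <- apply(m, 2, cumsum)
  aperm(array(m, dim(ap)), order(perm))
}

#' Sigmoid tumor-margin features
#'
#' Casts rays along outward surface normals at up to `n_rays` uniformly
#' sampled boundary voxels, samples the image from -5 mm (inside) to +5 mm
#' (outside) in 0.5 mm steps by trilinear interpolation, and fits
#' `I(x) = B + A / (1 + exp(-k (x - c)))` by Levenberg-Marquardt least
#' squares. Fits are canonicalized to `k > 0` (A is then the signed
#' inside-to-outside intensity step). The amplitude `A`, center `c` (mm) and
#' slope `k` (1/mm) of converged rays are aggregated with mean, median,
#' population SD, skewness, and the 2.5/97.5 percentiles: 3 x 6 = 18
#' features.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask].
#' @param n_rays Maximum number of boundary rays (default 150).
#' @return A named numeric vector of 18 values (`sigmoid_*`).
#' @export
sigmoid_margin_features <- function(img, mask, n_rays = 150L) {
  check_pair(img, mask)
  fits <- fit_margin_rays(img, mask, n_rays)
  if (nrow(fits) < 10) {
    stop("fewer than 10 converged sigmoid margin fits")
  }
  stats6 <- function(v) {
    n <- length(v)
    mu <- mean(v)
    s <- sqrt(sum((v - mu)^2) / n)
    qs <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
    c(mean = mu, median = qs[2], sd = s,
      skewness = if (s > 0) mean((v - mu)^3) / s^3 else 0,
      p2.5 = qs[1], p97.5 = qs[3])
  }
  out <- c(stats6(fits$amplitude), stats6(fits$center), stats6(fits$slope))
  names(out) <- paste0("sigmoid_",
                       rep(c("amplitude", "center", "slope"), each = 6), "_",
                       rep(c("mean", "median", "sd", "skewness", "p2.5",
                             "p97.5"), 3))
  out
}

# Fit the boundary-crossing sigmoid on each sampled ray; returns a data
# frame of converged fits.
fit_margin_rays <- function(img, mask, n_rays, reach_mm = 5, step_mm = 0.5) {
  m <- mask$data
  sp <- img$spacing
  sv <- surface_voxels(m)
  pts <- voxel_coords_mm(sv, sp)
  n_surf <- nrow(pts)
  take <- unique(round(seq(1, n_surf, length.out = min(n_rays, n_surf))))
  pts <- pts[take, , drop = FALSE]
  # outward normal: negative gradient of the smoothed indicator
  sm <- gaussian_smooth_3d(array(as.numeric(m), dim(m)), 2)
  grad <- lapply(1:3, function(ax) {
    (shift_valid(sm, -diag(3)[ax, ]) - shift_valid(sm, diag(3)[ax, ])) /
      (2 * sp[ax])
  })
  w <- which(sv, arr.ind = TRUE)[take, , drop = FALSE]
  gmat <- cbind(grad[[1]][w], grad[[2]][w], grad[[3]][w])
  nrm <- sqrt(rowSums(gmat^2))
  ok <- nrm > 0
  pts <- pts[ok, , drop = FALSE]
  normals <- -gmat[ok, , drop = FALSE] / nrm[ok]
  xs <- seq(-reach_mm, reach_mm, by = step_mm)
  res <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    ray <- pts[rep(i, length(xs)), , drop = FALSE] + outer(xs, normals[i, ])
    y <- trilinear_interp(img$data, sp, ray)
    f <- fit_sigmoid_profile(xs, y)
    if (!is.null(f)) res[[i]] <- f
  }
  do.call(rbind, c(list(data.frame(amplitude = numeric(0), center = numeric(0),
                                   slope = numeric(0))), res))
}

fit_sigmoid_profile <- function(x, y) {
  n <- length(y)
  b0 <- mean(y[1:3])
  a0 <- mean(y[(n - 2):n]) - b0
  fit <- tryCatch(
    suppressWarnings(
    minpack.lm::nlsLM(y ~ B + A / (1 + exp(-k * (x - c0))),
                      data = data.frame(x = x, y = y),
                      start = list(B = b0, A = a0, k = 1, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 60))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  if (!all(is.finite(cf))) return(NULL)
  A <- cf[["A"]]; B <- cf[["B"]]; k <- cf[["k"]]; c0 <- cf[["c0"]]
  if (k < 0) {  # mirror parameterization
    B <- B + A; A <- -A; k <- -k
  }
  if (abs(A) < 1e-8 || k == 0 || abs(c0) > max(abs(x))) return(NULL)
  data.frame(amplitude = A, center = c0, slope = k)
}

#' Laplacian-of-Gaussian filter features
#'
#' Convolves the full volume with 3D LoG kernels at sigma = 0.5..3.5 voxels
#' in 0.5 steps (index space, no resampling; mirror padding at the borders)
#' and computes 9 first-order statistics of the filtered values inside the
#' mask per scale: mean, population SD, skewness, kurtosis, median,
#' 2.5/97.5 percentiles, and entropy/uniformity on a 256-bin quantization.
#'
#' @param img A [rad_volume].
#' @param mask A [rad_mask].
#' @param sigmas LoG scales in voxels (default `log_sigmas()`).
#' @return A named numeric vector of `9 * length(sigmas)` values
#'   (`log_sigma{s}_{stat}`).
#' @export
log_filter_features <- function(img, mask, sigmas = log_sigmas()) {
  check_pair(img, mask)
  out <- numeric(0)
  stats9 <- c("mean", "sd", "skewness", "kurtosis", "median", "p2.5",
              "p97.5", "entropy", "uniformity")
  for (s in sigmas) {
    filt <- log_convolve(img$data, s)
    st <- first_order_stats(filt[mask$data])
    v <- unlist(st[stats9])
    names(v) <- paste0(sprintf("log_sigma%.1f", s), "_", stats9)
    out <- c(out, v)
  }
  out
}

# 3D LoG convolution with mirror padding, via FFT.
log_convolve <- function(a, sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- (-r):r
  g <- expand.grid(x = x, y = x, z = x)
  r2 <- g$x^2 + g$y^2 + g$z^2
  k <- (r2 - 3 * sigma^2) / sigma^4 *
    exp(-r2 / (2 * sigma^2)) / ((2 * pi)^(3/2) * sigma^3)
  k <- k - mean(k)  # enforce zero response to constants
  kern <- array(k, c(length(x), length(x), length(x)))
  d <- dim(a)
  pd <- d + 2L * r
  ap <- array(0, pd)
  mir <- function(n, r) c(pmin(n, r:1), 1:n, pmax(1, n:(n - r + 1)))
  ap <- a[mir(d[1], r), mir(d[2], r), mir(d[3], r)]
  kp <- array(0, pd)
  kp[1:(2 * r + 1), 1:(2 * r + 1), 1:(2 * r + 1)] <- kern
  # center the kernel at index (1,1,1) for circular convolution
  kp <- shift_array(kp, -c(r, r, r))
  conv <- Re(stats::fft(stats::fft(ap) * stats::fft(kp), inverse = TRUE)) /
    prod(pd)
  conv[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])]
}
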