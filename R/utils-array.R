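# Internal 3D array helpers shared across feature extractors.

# Separable Gaussian smoothing with mirror padding; sigma in voxels.
gaussian_smooth_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) a <- convolve_axis(a, k, r, axis)
  a
}

# 1D convolution of a 3D array along one axis, mirror padding.
convolve_axis <- function(a, k, r, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  n <- nrow(m)
  top <- m[pmin(n, r:1), , drop = FALSE]
  bot <- m[pmax(1L, n:(n - r + 1L)), , drop = FALSE]
  mp <- rbind(top, m, bot)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + n - 1L), , drop = FALSE]
  aperm(array(out, dim(ap)), order(perm))
}

# Integer-voxel circular shift along all three axes.
shift_array <- function(a, by) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    s <- ((seq_len(d[ax]) - 1L - by[ax]) %% d[ax]) + 1L
    s
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# The 26-neighborhood offsets (and the 13 unique half-space directions).
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

directions_13 <- function() {
  g <- neighbor_offsets_26()
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  g[keep, , drop = FALSE]
}

# Surface voxels: foreground with at least one 6-neighbor background
# (array border counts as background).
surface_voxels <- function(mask) {
  d <- dim(mask)
  pm <- array(FALSE, d + 2L)
  pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- pm[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pm[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pm[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pm[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pm[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pm[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pm[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  inner & !nb
}

# Voxel-center coordinates (mm) of TRUE voxels; 0-based indices times spacing.
voxel_coords_mm <- function(mask, spacing) {
  w <- which(mask, arr.ind = TRUE)
  sweep(w - 1L, 2, spacing, "*")
}

# Connected components of equal-valued in-mask voxels (26- or 6-connectivity)
# via igraph. Returns integer labels (0 outside mask).
label_components_3d <- function(levels, mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx_all <- which(mask)
  if (!length(idx_all)) return(lab)
  vox_id <- array(0L, d)
  vox_id[idx_all] <- seq_along(idx_all)
  offs <- if (connectivity == 26) directions_13() else {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  }
  lev <- array(levels, d)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    sm <- shift_valid(mask, o)
    sl <- shift_valid(lev, o)
    sid <- shift_valid(vox_id, o)
    ok <- mask & sm & (lev == sl)
    w <- which(ok)
    from <- c(from, vox_id[w]); to <- c(to, sid[w])
  }
  g <- igraph::make_graph(edges = as.vector(rbind(from, to)),
                          n = length(idx_all), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx_all] <- comp[seq_along(idx_all)]
  lab
}

# Shift an array by offset o, filling exposed planes with NA/0-like values.
shift_valid <- function(a, o) {
  d <- dim(a)
  fill <- if (is.logical(a)) FALSE else 0L
  out <- array(fill, d)
  if (any(abs(o) >= d)) return(out)  # shift larger than the axis: all fill
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (o[ax] >= 0) {
      src[[ax]] <- seq_len(d[ax] - o[ax])
      dst[[ax]] <- src[[ax]] + o[ax]
    } else {
      src[[ax]] <- (1 - o[ax]):d[ax]
      dst[[ax]] <- seq_len(d[ax] + o[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Trilinear interpolation of a 3D array at mm coordinates (0-based voxel
# centers at (i-1)*spacing). Points outside the grid are clamped.
trilinear_interp <- function(a, spacing, pts) {
  d <- dim(a)
  u <- sweep(pts, 2, spacing, "/")
  u <- pmax(u, 0)
  u <- sweep(u, 2, d - 1L, pmin)
  i0 <- pmin(floor(u), matrix(d - 2L, nrow(u), 3, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- u - i0
  gx <- i0[, 1] + 1L; gy <- i0[, 2] + 1L; gz <- i0[, 3] + 1L
  at <- function(dx, dy, dz) a[cbind(gx + dx, gy + dy, gz + dz)]
  c00 <- at(0L,0L,0L) * (1 - f[,1]) + at(1L,0L,0L) * f[,1]
  c10 <- at(0L,1L,0L) * (1 - f[,1]) + at(1L,1L,0L) * f[,1]
  c01 <- at(0L,0L,1L) * (1 - f[,1]) + at(1L,0L,1L) * f[,1]
  c11 <- at(0L,1L,1L) * (1 - f[,1]) + at(1L,1L,1L) * f[,1]
  c0 <- c00 * (1 - f[,2]) + c10 * f[,2]
  c1 <- c01 * (1 - f[,2]) + c11 * f[,2]
  c0 * (1 - f[,3]) + c1 * f[,3]
}
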