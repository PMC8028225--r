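# Independent brute-force oracles used to validate the vectorized
# implementations on tiny grids. These deliberately use plain nested loops
# and share no code with the package internals.

# All 26 neighbor offsets as a list.
oracle_offsets_26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx || dy || dz) out[[length(out) + 1]] <- c(dx, dy, dz)
  }
  out
}

# Brute-force pooled symmetric GLCM over all voxel pairs at Chebyshev
# distance 1, by scanning every voxel and every neighbor offset.
oracle_glcm_matrix <- function(lev, mask, n_levels) {
  d <- dim(mask)
  P <- matrix(0, n_levels, n_levels)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    for (o in oracle_offsets_26()) {
      xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
      if (!mask[xx, yy, zz]) next
      P[lev[x, y, z], lev[xx, yy, zz]] <- P[lev[x, y, z], lev[xx, yy, zz]] + 1
    }
  }
  P / sum(P)
}

# Brute-force GLCM statistics via explicit double loops.
oracle_glcm_stats <- function(P) {
  N <- nrow(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:N) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- 0; sy <- 0
  for (i in 1:N) { sx <- sx + (i - mux)^2 * px[i]; sy <- sy + (i - muy)^2 * py[i] }
  sx <- sqrt(sx); sy <- sqrt(sy)
  energy <- 0; entropy <- 0; contrast <- 0; homog <- 0; dissim <- 0
  corr_num <- 0; ssv <- 0; hxy1 <- 0
  psum <- rep(0, 2 * N); pdiff <- rep(0, N)
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * log2(p)
    contrast <- contrast + (i - j)^2 * p
    homog <- homog + p / (1 + abs(i - j))
    dissim <- dissim + abs(i - j) * p
    corr_num <- corr_num + (i - mux) * (j - muy) * p
    ssv <- ssv + (i - mux)^2 * p
    if (p > 0 && px[i] * py[j] > 0) hxy1 <- hxy1 - p * log2(px[i] * py[j])
    psum[i + j] <- psum[i + j] + p
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p
  }
  sum_avg <- 0; sum_ent <- 0; diff_ent <- 0
  for (k in seq_along(psum)) {
    sum_avg <- sum_avg + k * psum[k]
    if (psum[k] > 0) sum_ent <- sum_ent - psum[k] * log2(psum[k])
  }
  for (k in seq_along(pdiff)) {
    if (pdiff[k] > 0) diff_ent <- diff_ent - pdiff[k] * log2(pdiff[k])
  }
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  c(energy = energy, entropy = entropy, contrast = contrast,
    homogeneity = homog, dissimilarity = dissim,
    correlation = if (sx > 0 && sy > 0) corr_num / (sx * sy) else 1,
    imc1 = if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0,
    sum_of_squares_variance = ssv, sum_average = sum_avg,
    sum_entropy = sum_ent, difference_entropy = diff_ent)
}

# Brute-force 26-connected zone labeling by iterative set expansion.
oracle_glszm <- function(lev, mask) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z] || visited[x, y, z]) next
    g <- lev[x, y, z]
    frontier <- list(c(x, y, z))
    visited[x, y, z] <- TRUE
    size <- 0
    while (length(frontier)) {
      v <- frontier[[1]]; frontier <- frontier[-1]
      size <- size + 1
      for (o in oracle_offsets_26()) {
        w <- v + o
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && !visited[w[1], w[2], w[3]] &&
            lev[w[1], w[2], w[3]] == g) {
          visited[w[1], w[2], w[3]] <- TRUE
          frontier[[length(frontier) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = g, size = size)
  }
  zs <- do.call(rbind, zones)
  nz <- nrow(zs)
  by_size <- table(zs[, "size"])
  by_level <- table(zs[, "level"])
  c(size_zone_variability = sum(as.numeric(by_size)^2) / nz,
    intensity_variability = sum(as.numeric(by_level)^2) / nz)
}

# Brute-force NGTDM via per-voxel neighborhood averaging.
oracle_ngtdm <- function(lev, mask, n_levels, eps = 1e-6) {
  d <- dim(mask)
  s_i <- rep(0, n_levels); cnt <- rep(0, n_levels); n_tot <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (o in oracle_offsets_26()) {
      w <- c(x, y, z) + o
      if (any(w < 1) || any(w > d)) next
      if (mask[w[1], w[2], w[3]]) nb <- c(nb, lev[w[1], w[2], w[3]])
    }
    if (!length(nb)) next
    g <- lev[x, y, z]
    n_tot <- n_tot + 1
    cnt[g] <- cnt[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  p_i <- cnt / n_tot
  pres <- which(p_i > 0)
  Ng <- length(pres)
  ps <- sum(p_i * s_i)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  if (Ng > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
      complexity <- complexity +
        abs(i - j) * (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
      strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
    }
    contrast <- contrast / (Ng * (Ng - 1)) * sum(s_i) / n_tot
    complexity <- complexity / n_tot
    strength <- strength / (eps + sum(s_i))
  }
  c(coarseness = 1 / (eps + ps), contrast = contrast,
    busyness = if (busy_den > 0) ps / busy_den else 0,
    complexity = complexity, strength = strength)
}

# Product-limit estimator by explicit risk-set enumeration.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    deaths <- sum(time == ut[k] & event == 1)
    s <- s * (1 - deaths / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Breslow-ties Cox partial log-likelihood for a single covariate.
oracle_cox_loglik_1d <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Small deterministic random integer-level ROI for oracle comparisons.
random_quantized_grid <- function(seed, d = c(5, 5, 5), n_levels = 4,
                                  p_mask = 0.8) {
  set.seed(seed)
  mask <- array(runif(prod(d)) < p_mask, d)
  if (!any(mask)) mask[1] <- TRUE
  lev <- array(sample.int(n_levels, prod(d), replace = TRUE), d)
  lev[!mask] <- 0L
  list(lev = lev, mask = mask, n_levels = n_levels)
}
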