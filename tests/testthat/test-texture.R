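test_that("quantization covers edge cases", {
  dim3 <- c(3, 3, 3)
  q <- quantize(const_volume(dim3, 5), full_mask(dim3), 8)
  expect_true(all(q$grid[q$mask] == 1L))

  v <- rad_volume(array(seq(0, 26), dim3))
  q2 <- quantize(v, full_mask(dim3), 4)
  expect_equal(min(q2$grid[q2$mask]), 1L)
  expect_equal(max(q2$grid[q2$mask]), 4L)
  # maximum maps to the top level, not n_levels + 1
  expect_equal(q2$grid[3, 3, 3], 4L)
  # equal-width property: value just below the 1/4 break stays in level 1
  v3 <- rad_volume(array(c(0, 6.49, 6.51, 26, rep(13, 23)), dim3))
  q3 <- quantize(v3, full_mask(dim3), 4)
  expect_equal(q3$grid[2, 1, 1], 1L)
  expect_equal(q3$grid[3, 1, 1], 2L)

  # voxels outside the mask never receive a level
  m <- array(FALSE, dim3); m[1:5] <- TRUE
  q4 <- quantize(v, rad_mask(m), 4)
  expect_true(all(q4$grid[!m] == 0L))
})

test_that("GLCM on hand-computable fixtures", {
  # constant ROI: single cell P[1,1] = 1
  dim3 <- c(3, 3, 3)
  q <- quantize(const_volume(dim3, 2), full_mask(dim3), 256)
  st <- glcm_features(q)
  expect_equal(st[["glcm_energy"]], 1)
  expect_equal(st[["glcm_entropy"]], 0)
  expect_equal(st[["glcm_contrast"]], 0)
  expect_equal(st[["glcm_homogeneity"]], 1)
  expect_equal(st[["glcm_correlation"]], 1)  # degenerate convention
  expect_equal(st[["glcm_imc1"]], 0)

  # 1D alternating strip 1,2,1,2,...: every pair differs by exactly 1
  a <- array(0, c(8, 1, 1)); a[, 1, 1] <- rep(c(0, 10), 4)
  m <- array(FALSE, c(8, 1, 1)); m[, 1, 1] <- TRUE
  qs <- quantize(rad_volume(a), rad_mask(m), 2)
  ss <- glcm_features(qs)
  expect_equal(ss[["glcm_contrast"]], 1)
  expect_equal(ss[["glcm_dissimilarity"]], 1)
  expect_equal(ss[["glcm_homogeneity"]], 0.5)
})

test_that("GLCM matrix and statistics match the brute-force oracle", {
  for (seed in 1:12) {
    rq <- random_quantized_grid(seed, d = c(5, 4, 4), n_levels = 4)
    q <- list(grid = rq$lev, mask = rq$mask, n_levels = rq$n_levels)
    P <- glcm_matrix(q)
    P_o <- oracle_glcm_matrix(rq$lev, rq$mask, rq$n_levels)
    expect_equal(P, P_o, tolerance = 1e-12)
    st <- glcm_stats_from_matrix(P_o)
    st2 <- glcm_features(q)
    names(st2) <- sub("^glcm_", "", names(st2))
    expect_equal(st2[names(st)], st, tolerance = 1e-12)
  }
})

test_that("GLSZM matches the flood-fill oracle and hand fixtures", {
  for (seed in 1:8) {
    rq <- random_quantized_grid(seed + 100, d = c(4, 4, 4), n_levels = 3)
    q <- list(grid = rq$lev, mask = rq$mask, n_levels = rq$n_levels)
    got <- glszm_features(q)
    want <- oracle_glszm(rq$lev, rq$mask)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
  # constant ROI: one zone
  dim3 <- c(3, 3, 3)
  q <- quantize(const_volume(dim3, 1), full_mask(dim3), 32)
  g <- glszm_features(q)
  expect_equal(g[["glszm_size_zone_variability"]], 1)
  expect_equal(g[["glszm_intensity_variability"]], 1)
})

test_that("NGTDM matches the per-voxel oracle and its conventions", {
  for (seed in 1:8) {
    rq <- random_quantized_grid(seed + 200, d = c(4, 4, 4), n_levels = 5)
    q <- list(grid = rq$lev, mask = rq$mask, n_levels = rq$n_levels)
    got <- ngtdm_features(q)
    want <- oracle_ngtdm(rq$lev, rq$mask, rq$n_levels)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
  # constant ROI: coarseness hits the 1e6 cap, busyness 0
  dim3 <- c(3, 3, 3)
  q <- quantize(const_volume(dim3, 4), full_mask(dim3), 256)
  n <- ngtdm_features(q)
  expect_equal(n[["ngtdm_coarseness"]], 1e6)
  expect_equal(n[["ngtdm_busyness"]], 0)
  expect_equal(n[["ngtdm_contrast"]], 0)
})

test_that("sub-sampled ROI keeps the even sublattice and falls back when empty", {
  dim3 <- c(6, 6, 6)
  sub <- subsample_roi(full_mask(dim3))
  expect_equal(sum(sub$data), 27)  # 3 x 3 x 3 retained voxels
  idx <- which(sub$data, arr.ind = TRUE)
  expect_true(all((idx - 1) %% 2 == 0))

  # a mask living only on odd 0-based indices triggers the fallback
  m <- array(FALSE, dim3); m[2, 2, 2] <- TRUE
  expect_warning(sub2 <- subsample_roi(rad_mask(m)), "falling back")
  expect_identical(sub2$data, m)
})

test_that("texture_features returns the 29 named values and is deterministic", {
  ph <- cached_phantom()
  tx <- texture_features(ph$volume, ph$mask)
  expect_length(tx, 29)
  cat_tbl <- feature_catalog()
  expect_identical(names(tx), cat_tbl$name[cat_tbl$category == "texture"])
  expect_true(all(is.finite(tx)))
  expect_identical(tx, texture_features(ph$volume, ph$mask))
})

test_that("texture features are invariant to affine intensity rescaling", {
  ph <- cached_phantom()
  v2 <- rad_volume(ph$volume$data * 3 + 100, spacing = ph$volume$spacing)
  t1 <- texture_features(ph$volume, ph$mask)
  t2 <- texture_features(v2, ph$mask)
  expect_equal(t1, t2, tolerance = 1e-9)
})
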