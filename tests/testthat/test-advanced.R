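test_that("box-counting dimension matches reference geometries", {
  # straight line of voxels: dimension 1 exactly at dyadic scales
  line <- array(FALSE, c(32, 3, 3)); line[, 2, 2] <- TRUE
  expect_equal(box_counting_dimension(suppressWarnings(rad_mask(line))), 1,
               tolerance = 1e-10)

  # filled cube: dimension 3 exactly at dyadic scales
  cube <- array(TRUE, c(32, 32, 32))
  expect_equal(box_counting_dimension(rad_mask(cube)), 3, tolerance = 1e-10)

  # flat slab: dimension 2
  slab <- array(FALSE, c(32, 32, 3)); slab[, , 2] <- TRUE
  expect_equal(box_counting_dimension(rad_mask(slab)), 2, tolerance = 1e-10)

  # single voxel: N(eps) = 1 everywhere, slope 0
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  expect_equal(box_counting_dimension(rad_mask(one)), 0, tolerance = 1e-12)

  expect_error(box_counting_dimension(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("blanket FSD is zero for flat surfaces and translation invariant", {
  dim3 <- c(10, 10, 3)
  m <- array(FALSE, dim3); m[2:9, 2:9, 2] <- TRUE
  flat <- const_volume(dim3, 50)
  expect_equal(blanket_fsd(flat, rad_mask(m)), 0, tolerance = 1e-12)

  set.seed(3)
  img <- rad_volume(array(rnorm(prod(dim3), sd = 10), dim3))
  img2 <- rad_volume(img$data + 123.4)
  expect_equal(blanket_fsd(img, rad_mask(m)),
               blanket_fsd(img2, rad_mask(m)), tolerance = 1e-10)
})

test_that("blanket FSD matches an independent loop iteration on a small grid", {
  dim3 <- c(6, 6, 3)
  m <- array(FALSE, dim3); m[1:6, 1:6, 2] <- TRUE
  set.seed(11)
  h <- matrix(round(rnorm(36, sd = 5), 1), 6, 6)
  img <- rad_volume(array(c(h * 0, h, h * 0), dim3))

  # independent per-pixel loop implementation of the blanket recurrences
  u <- h; l <- h
  A <- numeric(5)
  for (e in 1:5) {
    un <- u; ln <- l
    for (i in 1:6) for (j in 1:6) {
      nb <- c()
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) nb <- c(nb, c(u[ii, jj]))
      }
      un[i, j] <- max(u[i, j] + 1, nb)
      nb2 <- c()
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6) nb2 <- c(nb2, l[ii, jj])
      }
      ln[i, j] <- min(l[i, j] - 1, nb2)
    }
    u <- un; l <- ln
    A[e] <- sum(u - l) / (2 * e)
  }
  slopes <- diff(log(A)) / diff(log(1:5))
  expect_equal(blanket_fsd(img, rad_mask(m)), max(slopes) - min(slopes),
               tolerance = 1e-12)
})

test_that("lacunarity obeys known values and a brute-force check", {
  expect_equal(lacunarity(full_mask(c(6, 6, 6))), 1, tolerance = 1e-12)

  set.seed(5)
  m <- array(runif(6^3) < 0.5, c(6, 6, 6))
  m[1, 1, 1] <- TRUE; m[6, 6, 6] <- TRUE  # pin the bounding box
  got <- lacunarity(suppressWarnings(rad_mask(m)), r = 3)
  # brute force over all 4^3 boxes
  masses <- c()
  for (x in 1:4) for (y in 1:4) for (z in 1:4) {
    masses <- c(masses, sum(m[x:(x + 2), y:(y + 2), z:(z + 2)]))
  }
  expect_equal(got, mean(masses^2) / mean(masses)^2, tolerance = 1e-12)
  expect_gte(got, 1)

  expect_error(lacunarity(rad_mask(array(TRUE, c(2, 2, 2))), r = 3), "smaller")
})

test_that("sigmoid margin fits recover a known margin slope", {
  ph <- make_tumor_phantom(semi_axes = c(10, 10, 10), texture_sd = 0,
                           margin_slope = 1.5, seed = 1)
  sg <- sigmoid_margin_features(ph$volume, ph$mask)
  expect_length(sg, 18)
  expect_lt(abs(sg[["sigmoid_slope_mean"]] - 1 / 1.5) / (1 / 1.5), 0.1)
  # amplitude is the signed inside-to-outside step: negative for a hot core
  expect_lt(sg[["sigmoid_amplitude_mean"]], 0)
  expect_lt(abs(sg[["sigmoid_amplitude_mean"]] - (-890)) / 890, 0.1)
  # center near the nominal boundary
  expect_lt(abs(sg[["sigmoid_center_mean"]]), 1)
})

test_that("sigmoid fitting canonicalizes to positive slope", {
  x <- seq(-5, 5, by = 0.5)
  y_up <- 10 + 50 / (1 + exp(-2 * (x - 0.3)))
  f <- fit_sigmoid_profile(x, y_up)
  expect_equal(f$slope, 2, tolerance = 1e-6)
  expect_equal(f$amplitude, 50, tolerance = 1e-6)
  expect_equal(f$center, 0.3, tolerance = 1e-6)
  y_dn <- 60 - 50 / (1 + exp(-2 * (x - 0.3)))
  f2 <- fit_sigmoid_profile(x, y_dn)
  expect_gt(f2$slope, 0)
  expect_equal(f2$amplitude, -50, tolerance = 1e-6)
  # flat profile is rejected rather than reported
  expect_null(fit_sigmoid_profile(x, rep(5, length(x))))
})

test_that("LoG filtering annihilates constants and linear ramps", {
  dim3 <- c(16, 16, 16)
  flat <- log_convolve(array(7, dim3), 1.5)
  expect_lt(max(abs(flat)), 1e-9)

  ramp <- array(rep(seq_len(16), times = 256), dim3)  # linear in x
  resp <- log_convolve(ramp, 1.0)
  interior <- resp[6:11, 6:11, 6:11]  # away from mirror-padded borders
  expect_lt(max(abs(interior)), 1e-8)
})

test_that("LoG features have the documented names and respond to blobs", {
  ph <- cached_phantom()
  lf <- log_filter_features(ph$volume, ph$mask)
  expect_length(lf, 63)
  cat_tbl <- feature_catalog()
  expect_identical(names(lf), cat_tbl$name[cat_tbl$category == "filter"])
  expect_true(all(is.finite(lf)))
  # a textured image must give nonzero LoG dispersion at every scale
  sds <- lf[grepl("_sd$", names(lf))]
  expect_true(all(sds > 0))
})
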