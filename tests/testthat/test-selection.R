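test_that("ICC(2,1) behaves on canonical fixtures", {
  # perfect agreement
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(as.numeric(icc(x)), 1)

  # identical constant raters: degenerate, reported as 1
  xc <- cbind(rep(5, 4), rep(5, 4))
  expect_equal(as.numeric(icc(xc)), 1)
  expect_true(isTRUE(attr(icc(xc), "degenerate")))

  # a systematic offset lowers absolute agreement even with perfect rank
  # consistency, and the penalty shrinks as subject variance grows
  off_small <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4) + 2)
  off_large <- cbind(c(10, 20, 30, 40), c(10, 20, 30, 40) + 2)
  expect_lt(as.numeric(icc(off_small)), 1)
  expect_lt(as.numeric(icc(off_small)), as.numeric(icc(off_large)))

  # hand-computed mean squares on a 3 x 2 table
  xh <- cbind(c(1, 5, 9), c(2, 4, 10))
  n <- 3; k <- 2
  g <- mean(xh); ri <- rowMeans(xh); cj <- colMeans(xh)
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  mse <- sum((xh - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + g)^2) /
    ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(as.numeric(icc(xh)), want, tolerance = 1e-12)

  # independent raters: ICC near 0 at large n
  set.seed(9)
  xr <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(as.numeric(icc(xr))), 0.2)

  expect_error(icc(cbind(1:2, 1:2)), "nrow")
})

test_that("the ICC filter applies a strict threshold", {
  set.seed(2)
  base <- tibble::tibble(subject_id = sprintf("s%02d", 1:30),
                         good = rnorm(30, sd = 10),
                         bad = rnorm(30))
  retest <- base
  retest$good <- base$good + rnorm(30, sd = 0.5)   # high ICC
  retest$bad <- rnorm(30)                          # near-zero ICC
  flt <- icc_filter(base, retest, threshold = 0.9)
  expect_true(flt$stable[flt$feature == "good"])
  expect_false(flt$stable[flt$feature == "bad"])
  expect_identical(stable_features(base, retest), "good")

  # strictness: a feature with ICC exactly at the threshold is excluded
  flt2 <- icc_filter(base, base, threshold = 1)
  expect_false(any(flt2$stable))

  bad_cols <- base; names(bad_cols)[2] <- "other"
  expect_error(icc_filter(bad_cols, retest), "mismatched feature")
})

test_that("Cox-LASSO path has the expected limiting behavior", {
  fx <- simulate_feature_table(120, c("f1", "f2", "f3"), seed = 5)
  co <- simulate_survival(fx, beta = c(f1 = 1, f2 = 0, f3 = 0),
                          baseline_rate = 0.02, censor_rate = 0.005, seed = 6)
  path <- cox_lasso_path(co)
  # very large lambda: all coefficients zero
  b_inf <- cox_lasso_coef(path, s = 1e6)
  expect_true(all(b_inf == 0))
  # near-zero lambda: the planted feature is active and dominant
  b0 <- cox_lasso_coef(path, s = 1e-4)
  expect_gt(abs(b0[["f1"]]), abs(b0[["f2"]]))
  expect_gt(abs(b0[["f1"]]), abs(b0[["f3"]]))
  expect_gt(b0[["f1"]], 0.5)
})

test_that("unpenalized single-feature limit matches the Breslow oracle", {
  fx <- simulate_feature_table(60, "f1", seed = 15)
  co <- simulate_survival(fx, beta = c(f1 = 0.8), baseline_rate = 0.02,
                          censor_rate = 0.005, seed = 16)
  x <- as.numeric(scale(co$f1))
  # maximize the hand-written Breslow partial likelihood
  opt <- stats::optimize(function(b) -oracle_cox_loglik_1d(b, x, co$time,
                                                           co$event),
                         c(-5, 5))
  path <- cox_lasso_path(co, "f1", lambda = c(0.05, 1e-6))
  b_hat <- cox_lasso_coef(path, s = 1e-6)[["f1"]]
  expect_equal(b_hat, opt$minimum, tolerance = 1e-3)
  # and coxph agrees with both
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = co,
                         ties = "breslow")
  expect_equal(unname(coef(fit)), opt$minimum, tolerance = 1e-4)
})

test_that("cv_lambda is deterministic given the seed and checks folds", {
  fx <- simulate_feature_table(80, c("f1", "f2"), seed = 25)
  co <- simulate_survival(fx, beta = c(f1 = 1, f2 = 0), baseline_rate = 0.02,
                          censor_rate = 0.005, seed = 26)
  a <- cv_lambda(co, folds = 5, seed = 7)
  b <- cv_lambda(co, folds = 5, seed = 7)
  expect_identical(a$lambda, b$lambda)
  expect_identical(a$foldid, b$foldid)
  c_ <- cv_lambda(co, folds = 5, seed = 8)
  expect_false(identical(a$foldid, c_$foldid))
  expect_error(cv_lambda(co, folds = 2), "folds")
})

test_that("repeated selection keeps planted features and drops pure noise", {
  fx <- simulate_feature_table(250, paste0("f", 1:8), seed = 35)
  co <- simulate_survival(fx, beta = c(f1 = 1.5, f2 = -1.5),
                          baseline_rate = 0.02, censor_rate = 0.005,
                          seed = 36)
  sel <- select_features(co, n_repeats = 6, count_threshold = 3,
                         cv_folds = 5, seed = 40)
  expect_s3_class(sel, "rad_selection")
  expect_true(all(c("f1", "f2") %in% sel$final_features))
  expect_equal(sign(sel$coefficients[["f1"]]), 1)
  expect_equal(sign(sel$coefficients[["f2"]]), -1)

  td <- tidy(sel)
  expect_identical(names(td),
                   c("feature", "count", "selected", "coefficient"))
  expect_true(all(is.na(td$coefficient[!td$selected])))
  gl <- glance(sel)
  expect_equal(gl$n_candidates, 8)
  expect_equal(gl$n_selected, length(sel$final_features))

  # determinism of the whole procedure
  sel2 <- select_features(co, n_repeats = 6, count_threshold = 3,
                          cv_folds = 5, seed = 40)
  expect_identical(sel$counts, sel2$counts)
  expect_identical(sel$coefficients, sel2$coefficients)
})

test_that("train mode is strict and variant mode is inclusive at the threshold", {
  counts <- c(a = 10L, b = 11L)
  keep_train <- names(counts)[counts > 10]
  keep_variant <- names(counts)[counts >= 10]
  expect_identical(keep_train, "b")
  expect_identical(keep_variant, c("a", "b"))
})
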