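make_model <- function(features, coefficients, mean = 0, sd = 1) {
  structure(list(
    features = features,
    coefficients = stats::setNames(coefficients, features),
    standardization = tibble::tibble(feature = features,
                                     mean = rep_len(mean, length(features)),
                                     sd = rep_len(sd, length(features))),
    exclusions = character(0)),
    class = "rad_score_model")
}

test_that("the radiomics score is the stated linear combination", {
  tbl <- tibble::tibble(f1 = c(0, 2, 4), f2 = c(10, 10, 16))
  model <- make_model(c("f1", "f2"), c(0.5, -1),
                      mean = c(2, 12), sd = c(2, 3))
  model$standardization <- tibble::tibble(feature = c("f1", "f2"),
                                          mean = c(2, 12), sd = c(2, 3))
  sc <- radiomics_score(tbl, model)
  z1 <- (tbl$f1 - 2) / 2; z2 <- (tbl$f2 - 12) / 3
  expect_equal(sc$score, 0.5 * z1 - 1 * z2)

  # empty model: score 0
  empty <- make_model(character(0), numeric(0))
  expect_equal(radiomics_score(tbl, empty)$score, c(0, 0, 0))

  expect_error(radiomics_score(tbl[, "f1"], model), "missing features")
})

test_that("excluding a feature equals setting its coefficient to zero", {
  set.seed(1)
  tbl <- tibble::tibble(f1 = rnorm(10), f2 = rnorm(10))
  m_full <- make_model(c("f1", "f2"), c(0.7, 1.2))
  m_zero <- make_model(c("f1", "f2"), c(0.7, 0))
  sel_like <- structure(list(final_features = c("f1", "f2"),
                             coefficients = c(f1 = 0.7, f2 = 1.2),
                             standardization = m_full$standardization),
                        class = "rad_selection")
  m_excl <- build_score_model(sel_like, exclude = "f2")
  expect_identical(m_excl$features, "f1")
  expect_equal(radiomics_score(tbl, m_excl)$score,
               radiomics_score(tbl, m_zero)$score)
})

test_that("median split assigns ties and the low group correctly", {
  sc <- tibble::tibble(score = c(1, 2, 3, 4))
  grp <- median_split(sc)
  expect_equal(attr(grp, "cutoff"), 2.5)
  expect_identical(as.character(grp$risk_group), c("low", "low", "high", "high"))

  # a score equal to the median goes to the low-risk group
  sc2 <- tibble::tibble(score = c(1, 2, 2, 2, 5))
  grp2 <- median_split(sc2)
  expect_identical(as.character(grp2$risk_group),
                   c("low", "low", "low", "low", "high"))

  # constant scores: everyone low, flagged degenerate
  grp3 <- median_split(tibble::tibble(score = rep(3, 5)))
  expect_true(attr(grp3, "degenerate"))
  expect_true(all(grp3$risk_group == "low"))

  expect_error(median_split(tibble::tibble(score = 1:3)), "nrow")
})

test_that("Kaplan-Meier matches the hand fixture and the oracle", {
  # times 1, 2, 3, all events: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(3, 2, 1))

  # censoring removes subjects without a step
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$n_event == 1], c(2/3, 0), tolerance = 1e-12)

  # all censored: survival stays at 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))

  # randomized comparison against the risk-set enumeration oracle
  set.seed(77)
  tm <- sample(1:20, 40, replace = TRUE)
  ev <- rbinom(40, 1, 0.7)
  km4 <- km_estimate(tm, ev)
  orc <- oracle_km(tm, ev)
  got <- km4[km4$n_event > 0, c("time", "surv")]
  expect_equal(got$time, orc$time)
  expect_equal(got$surv, orc$surv, tolerance = 1e-12)
})

test_that("log-rank test on hand fixtures", {
  # identical groups interleaved: statistic 0, p = 1
  tm <- c(1, 1, 2, 2, 3, 3)
  ev <- rep(1, 6)
  gr <- rep(c("a", "b"), 3)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # hand-computed two-group fixture: group a dies at 1, 2; group b at 3, 4
  # observed events in a = 2; E_a = 2/4 + 2/3 (only a at risk afterwards)
  tm2 <- c(1, 2, 3, 4); ev2 <- rep(1, 4); gr2 <- c("a", "a", "b", "b")
  o_a <- 2; e_a <- 2/4 + 1/3
  v_a <- (2 * 2 * 1 * (4 - 1)) / (4^2 * (4 - 1)) +
    (2 * 1 * 1 * (3 - 1)) / (3^2 * (3 - 1))
  stat <- (o_a - e_a)^2 / v_a
  lr2 <- logrank_test(tm2, ev2, gr2)
  expect_equal(lr2$statistic, stat, tolerance = 1e-10)
  expect_equal(lr2$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # zero events: degenerate p = 1
  lr3 <- logrank_test(tm, rep(0, 6), gr)
  expect_true(lr3$degenerate)
  expect_equal(lr3$p_value, 1)

  expect_error(logrank_test(tm, ev, rep("a", 6)), "two non-empty groups")
})

test_that("stratification is equivariant to positive affine score changes", {
  fx <- simulate_feature_table(60, "f1", seed = 51)
  co <- simulate_survival(fx, beta = c(f1 = 1), baseline_rate = 0.02,
                          censor_rate = 0.005, seed = 52)
  m1 <- make_model("f1", 1)
  m2 <- make_model("f1", 3)  # positive rescaling of the score
  r1 <- stratify_cohort(co, m1)
  r2 <- stratify_cohort(co, m2)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("transfer_experiment stratifies matched outcomes, not mismatched ones", {
  set.seed(61)
  fx <- simulate_feature_table(150, paste0("f", 1:5), seed = 61)
  co <- simulate_survival(fx, beta = c(f1 = 1.5), baseline_rate = 0.02,
                          censor_rate = 0.005, seed = 62)
  fx_t <- simulate_feature_table(60, paste0("f", 1:5), seed = 63)
  matched <- simulate_survival(fx_t, beta = c(f1 = 1.5), baseline_rate = 0.02,
                               censor_rate = 0.005, seed = 64)
  mismatched <- simulate_survival(fx_t, beta = c(f5 = 0), baseline_rate = 0.02,
                                  censor_rate = 0.005, seed = 65)
  out <- transfer_experiment(co, list(matched = matched,
                                      mismatched = mismatched),
                             n_repeats = 6, count_threshold = 3, cv_folds = 5,
                             seed = 66)
  expect_identical(out$results$cohort, c("train", "matched", "mismatched"))
  expect_true("f1" %in% out$model$features)
  p <- out$results$p_value
  expect_lt(p[out$results$cohort == "train"], 0.01)
  expect_lt(p[out$results$cohort == "matched"], 0.05)
  expect_gt(p[out$results$cohort == "mismatched"], 0.01)
})
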