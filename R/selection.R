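# Two-step feature selection: ICC stability filter on test-retest feature
# tables, then repeated cross-validated Cox-LASSO with a selection-count
# threshold.

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way, absolute-agreement, single-measurement ICC computed from the
#' mean squares of the two-way subject x rater layout, clamped to
#' `[-1, 1]`. With zero total variance (identical constant raters) the ICC
#' is returned as 1 with attribute `degenerate = TRUE`.
#'
#' @param x Numeric matrix with one row per subject and two columns
#'   (test, retest); at least 3 subjects.
#' @return The ICC (scalar).
#' @export
icc <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2, nrow(x) >= 3)
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  if (sum((x - g)^2) == 0) {
    return(structure(1, degenerate = TRUE))
  }
  msr <- k * sum((ri - g)^2) / (n - 1)
  msc <- n * sum((cj - g)^2) / (k - 1)
  mse <- sum((x - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + g)^2) /
    ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  max(-1, min(1, val))
}

#' ICC stability filter over a test-retest feature-table pair
#'
#' Computes the ICC of every shared feature column and flags features with
#' ICC strictly above the threshold as stable.
#'
#' @param test,retest Tibbles with `subject_id` and feature columns;
#'   matching subjects and features.
#' @param threshold Stability threshold (default 0.9, strict inequality).
#' @return A tibble with columns `feature`, `icc`, `stable`, in catalog
#'   (input) order.
#' @export
icc_filter <- function(test, retest, threshold = 0.9) {
  fcols <- setdiff(names(test), "subject_id")
  if (!identical(fcols, setdiff(names(retest), "subject_id"))) {
    stop("test and retest tables have mismatched feature columns")
  }
  if (!identical(test$subject_id, retest$subject_id)) {
    stop("test and retest tables have mismatched subjects")
  }
  vals <- vapply(fcols, function(f) {
    as.numeric(icc(cbind(test[[f]], retest[[f]])))
  }, 0)
  tibble::tibble(feature = fcols, icc = vals, stable = vals > threshold)
}

#' Names of ICC-stable features
#'
#' @inheritParams icc_filter
#' @return Character vector of features with ICC above the threshold,
#'   order preserved.
#' @export
stable_features <- function(test, retest, threshold = 0.9) {
  flt <- icc_filter(test, retest, threshold)
  flt$feature[flt$stable]
}

# Standardize feature columns to mean 0 / SD 1; constant columns are
# dropped with a warning. Returns the matrix plus the constants used.
standardize_features <- function(cohort, features) {
  x <- as.matrix(cohort[features])
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping constant features: ",
            paste(features[!keep], collapse = ", "))
  }
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep], "/")
  list(x = x, mean = mu[keep], sd = sds[keep], features = features[keep])
}

#' Cox-LASSO coefficient path
#'
#' L1-penalized Cox regression (Breslow ties, internally standardized
#' features) along a decreasing lambda grid via glmnet.
#'
#' @param cohort Tibble with `time`, `event` and feature columns.
#' @param features Feature names to include (default: all non-outcome
#'   columns).
#' @param lambda Optional lambda grid (decreasing positive reals); by
#'   default glmnet's data-driven path.
#' @return A list with the `glmnet` `fit`, the `lambda` grid, and the
#'   standardization constants.
#' @export
cox_lasso_path <- function(cohort, features = NULL, lambda = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(cohort), c("subject_id", "time", "event"))
  }
  if (sum(cohort$event) < 1) stop("no events in cohort")
  st <- standardize_features(cohort, features)
  x <- st$x
  single <- ncol(x) == 1L
  if (single) x <- cbind(x, .dummy = 0)  # glmnet needs >= 2 columns
  y <- survival::Surv(cohort$time, cohort$event)
  fit <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE,
                        lambda = lambda)
  list(fit = fit, lambda = fit$lambda, standardization = st,
       single = single)
}

#' Coefficients of a Cox-LASSO path at a given lambda
#'
#' @param path A path from [cox_lasso_path()].
#' @param s Lambda value.
#' @return Named numeric vector of coefficients (standardized scale).
#' @export
cox_lasso_coef <- function(path, s) {
  b <- as.matrix(stats::coef(path$fit, s = s, exact = FALSE))[, 1]
  if (path$single) b <- b[setdiff(names(b), ".dummy")]
  b
}

#' Cross-validated lambda for the Cox-LASSO
#'
#' Selects the lambda minimizing the cross-validated Cox partial-likelihood
#' deviance over seeded fold assignments. Fold assignments with an
#' event-free fold are redrawn (with a warning after repeated failures).
#'
#' @param cohort Tibble with `time`, `event` and feature columns.
#' @param features Feature names (default all non-outcome columns).
#' @param folds Number of CV folds (>= 3).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `lambda` (the selected value), `cvfit` and the fold
#'   assignment.
#' @export
cv_lambda <- function(cohort, features = NULL, folds = 10L, seed = 1L) {
  stopifnot(folds >= 3)
  if (is.null(features)) {
    features <- setdiff(names(cohort), c("subject_id", "time", "event"))
  }
  st <- standardize_features(cohort, features)
  x <- st$x
  if (ncol(x) == 1L) x <- cbind(x, .dummy = 0)
  y <- survival::Surv(cohort$time, cohort$event)
  n <- nrow(x)
  set.seed(seed)
  foldid <- NULL
  for (try in 1:25) {
    cand <- sample(rep_len(seq_len(folds), n))
    ev_per_fold <- tapply(cohort$event, cand, sum)
    if (all(ev_per_fold > 0)) { foldid <- cand; break }
  }
  if (is.null(foldid)) {
    warning("could not build folds with events in every fold; using last draw")
    foldid <- cand
  }
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", standardize = FALSE,
                             foldid = foldid, type.measure = "deviance")
  list(lambda = cvfit$lambda.min, cvfit = cvfit, foldid = foldid)
}

#' Repeated Cox-LASSO stability selection
#'
#' Repeats cross-validated Cox-LASSO `n_repeats` times with distinct
#' sub-seeds (the fold assignment is the only stochastic element),
#' accumulates per-feature selection counts from the nonzero pattern at each
#' repeat's optimal lambda, and keeps features whose count passes the
#' threshold: strictly greater in `"train"` mode (more than 10 of 20), or
#' at least the threshold in `"variant"` mode (10 of 40). Coefficients for
#' the final set are refit by unpenalized Cox regression (Breslow ties) on
#' the standardized features.
#'
#' @param cohort Tibble with `time`, `event` and feature columns (already
#'   ICC-filtered).
#' @param features Feature names to consider.
#' @param n_repeats Number of repeats (20 train / 40 variant).
#' @param count_threshold Selection-count threshold (default 10).
#' @param mode `"train"` (count > threshold) or `"variant"`
#'   (count >= threshold).
#' @param cv_folds CV folds per repeat.
#' @param seed Master seed; repeat `i` uses `seed + i`.
#' @return An object of class `rad_selection` with selection counts, the
#'   final feature set, refit coefficients and standardization constants.
#' @export
select_features <- function(cohort, features = NULL, n_repeats = 20L,
                            count_threshold = 10L,
                            mode = c("train", "variant"), cv_folds = 10L,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(features)) {
    features <- setdiff(names(cohort), c("subject_id", "time", "event"))
  }
  st <- standardize_features(cohort, features)
  feats <- st$features
  counts <- stats::setNames(integer(length(feats)), feats)
  lambdas <- numeric(n_repeats)
  path <- cox_lasso_path(cohort, feats)
  for (i in seq_len(n_repeats)) {
    cv <- cv_lambda(cohort, feats, folds = cv_folds, seed = seed + i)
    lambdas[i] <- cv$lambda
    b <- cox_lasso_coef(path, cv$lambda)
    nz <- names(b)[b != 0]
    counts[nz] <- counts[nz] + 1L
  }
  final <- if (mode == "train") {
    names(counts)[counts > count_threshold]
  } else {
    names(counts)[counts >= count_threshold]
  }
  coefs <- refit_cox(cohort, final, st)
  structure(list(
    counts = tibble::tibble(feature = feats, count = as.integer(counts),
                            selected = feats %in% final),
    final_features = final,
    coefficients = coefs,
    standardization = tibble::tibble(feature = st$features, mean = st$mean,
                                     sd = st$sd),
    n_repeats = n_repeats, count_threshold = count_threshold, mode = mode,
    lambdas = lambdas, seed = seed),
    class = "rad_selection")
}

# Unpenalized Cox refit (Breslow ties) on standardized features.
refit_cox <- function(cohort, final, st) {
  if (!length(final)) return(stats::setNames(numeric(0), character(0)))
  idx <- match(final, st$features)
  x <- sweep(sweep(as.matrix(cohort[final]), 2, st$mean[idx]), 2,
             st$sd[idx], "/")
  df <- data.frame(x, check.names = FALSE)
  df$time <- cohort$time; df$event <- cohort$event
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", final),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  stats::setNames(as.numeric(stats::coef(fit)), final)
}

#' @export
print.rad_selection <- function(x, ...) {
  cat(sprintf("<rad_selection> %d repeats, rule: count %s %d\n", x$n_repeats,
              if (x$mode == "train") ">" else ">=", x$count_threshold))
  cat(sprintf("  %d candidate features -> %d selected\n",
              nrow(x$counts), length(x$final_features)))
  if (length(x$final_features)) {
    print(utils::head(dplyr::arrange(x$counts[x$counts$selected, ],
                                     dplyr::desc(.data$count)), 10))
  }
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x A `rad_selection`.
#' @param ... Unused.
#' @return Tibble of per-feature selection counts, flags, and refit
#'   coefficients (NA for unselected features).
#' @importFrom generics tidy
#' @method tidy rad_selection
#' @export
tidy.rad_selection <- function(x, ...) {
  dplyr::mutate(x$counts,
                coefficient = unname(x$coefficients[x$counts$feature]))
}

#' One-row summary of a selection result
#'
#' @param x A `rad_selection`.
#' @param ... Unused.
#' @importFrom generics glance
#' @method glance rad_selection
#' @export
glance.rad_selection <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x$counts),
                 n_selected = length(x$final_features),
                 n_repeats = x$n_repeats,
                 count_threshold = x$count_threshold,
                 mode = x$mode)
}
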