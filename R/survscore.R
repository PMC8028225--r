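# Radiomics score, median-split risk groups, Kaplan-Meier, log-rank, and
# the cross-organ transfer experiment.

#' Build a radiomics score model from a selection result
#'
#' The score is the linear combination of standardized selected feature
#' values weighted by the (refit) Cox coefficients. An exclusion list drops
#' features from the score (e.g. removing a lung-specific feature such as
#' the 2.5 percentile before transferring to other organs).
#'
#' @param selection A `rad_selection` from [select_features()].
#' @param exclude Optional character vector of feature names to exclude.
#' @return An object of class `rad_score_model`.
#' @export
build_score_model <- function(selection, exclude = NULL) {
  feats <- setdiff(selection$final_features, exclude)
  std <- selection$standardization
  structure(list(
    features = feats,
    coefficients = selection$coefficients[feats],
    standardization = std[std$feature %in% feats, ],
    exclusions = exclude %||% character(0)),
    class = "rad_score_model")
}

#' Refit a score model's coefficients on another cohort
#'
#' Keeps the same feature names but re-standardizes on the target cohort
#' and refits the coefficients by unpenalized Cox regression (Breslow
#' ties) there — the transfer convention of evaluating a trained feature
#' set on a new organ.
#'
#' @param model A `rad_score_model`.
#' @param cohort Tibble with `time`, `event` and the model's feature
#'   columns.
#' @return A new `rad_score_model` fitted to `cohort`.
#' @export
refit_score_model <- function(model, cohort) {
  feats <- model$features
  missing <- setdiff(feats, names(cohort))
  if (length(missing)) {
    stop("selected features absent in cohort: ",
         paste(missing, collapse = ", "))
  }
  if (!length(feats)) return(model)
  st <- standardize_features(cohort, feats)
  coefs <- refit_cox(cohort, st$features, st)
  structure(list(features = st$features, coefficients = coefs,
                 standardization = tibble::tibble(feature = st$features,
                                                  mean = st$mean,
                                                  sd = st$sd),
                 exclusions = model$exclusions),
            class = "rad_score_model")
}

#' @export
print.rad_score_model <- function(x, ...) {
  cat(sprintf("<rad_score_model> %d features", length(x$features)))
  if (length(x$exclusions)) {
    cat(" (excluding ", paste(x$exclusions, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  if (length(x$features)) {
    print(tibble::tibble(feature = x$features,
                         coefficient = unname(x$coefficients)))
  }
  invisible(x)
}

#' Compute radiomics scores for a cohort
#'
#' Adds a `score` column: the sum of coefficient times standardized feature
#' value over the model's (non-excluded) features. An empty model yields
#' score 0 for everyone.
#'
#' @param features Tibble with the model's feature columns.
#' @param model A `rad_score_model`.
#' @return The input tibble with a `score` column appended.
#' @export
radiomics_score <- function(features, model) {
  missing <- setdiff(model$features, names(features))
  if (length(missing)) {
    stop("missing features for scoring: ", paste(missing, collapse = ", "))
  }
  n <- nrow(features)
  if (!length(model$features)) {
    return(dplyr::mutate(features, score = 0))
  }
  std <- model$standardization
  x <- as.matrix(features[model$features])
  z <- sweep(sweep(x, 2, std$mean[match(model$features, std$feature)]), 2,
             std$sd[match(model$features, std$feature)], "/")
  dplyr::mutate(features,
                score = as.vector(z %*% model$coefficients[model$features]))
}

#' Median-split risk grouping
#'
#' Subjects with score less than or equal to the sample median (mean of the
#' middle two order statistics for even n) form the low-risk group; the
#' rest are high-risk. When all scores are identical everyone is low-risk
#' and the result is flagged degenerate.
#'
#' @param scores Tibble with a `score` column (n >= 4).
#' @return The input tibble with a `risk_group` factor (`low`, `high`);
#'   attributes `cutoff` (the median) and `degenerate`.
#' @export
median_split <- function(scores) {
  stopifnot(nrow(scores) >= 4)
  med <- stats::median(scores$score)
  grp <- factor(ifelse(scores$score <= med, "low", "high"),
                levels = c("low", "high"))
  out <- dplyr::mutate(scores, risk_group = grp)
  attr(out, "cutoff") <- med
  attr(out, "degenerate") <- length(unique(scores$score)) == 1L
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function; censored subjects
#' leave the risk set without a step.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A tibble with `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with 1 degree of freedom; the
#' p-value is the upper chi-square tail. With zero events the statistic is
#' 0 and p = 1 (flagged).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators.
#' @param group Two-level grouping vector.
#' @return A tibble with `statistic`, `df`, `p_value`, `degenerate`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop("log-rank test needs exactly two non-empty groups")
  if (sum(event) == 0) {
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1,
                          degenerate = TRUE))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd_$chisq
  tibble::tibble(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 degenerate = FALSE)
}

#' Risk stratification of one cohort under a score model
#'
#' Scores the cohort, median-splits it, and compares the two risk groups
#' with the log-rank test.
#'
#' @param cohort Tibble with `time`, `event` and the model's features.
#' @param model A `rad_score_model`.
#' @return A one-row tibble: `n`, `n_events`, `cutoff`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
stratify_cohort <- function(cohort, model) {
  sc <- median_split(radiomics_score(cohort, model))
  if (attr(sc, "degenerate")) {
    return(tibble::tibble(n = nrow(sc), n_events = sum(sc$event),
                          cutoff = attr(sc, "cutoff"), statistic = 0,
                          p_value = 1, degenerate = TRUE))
  }
  lr <- logrank_test(sc$time, sc$event, sc$risk_group)
  tibble::tibble(n = nrow(sc), n_events = sum(sc$event),
                 cutoff = attr(sc, "cutoff"), statistic = lr$statistic,
                 p_value = lr$p_value, degenerate = lr$degenerate)
}

#' Cross-organ transfer experiment
#'
#' Selects features on the training cohort (restricted to the ICC-stable
#' set when given), builds the radiomics score, and evaluates risk
#' stratification on the training cohort and each test cohort. By default
#' the frozen training score (training standardization and coefficients) is
#' applied to each test cohort (`refit = FALSE`); setting `refit = TRUE`
#' instead re-standardizes and refits the coefficients on each test cohort
#' before stratifying it. Note that refitting and testing on the same
#' cohort is in-sample evaluation and inflates apparent significance. An
#' exclusion list reruns the score without the named features.
#'
#' @param train_cohort Tibble with `subject_id`, features, `time`, `event`.
#' @param test_cohorts Named list of test cohort tibbles.
#' @param stable Character vector of ICC-stable feature names (default: all
#'   features).
#' @param exclude Features excluded from the score (e.g. `"hist_p2.5"`).
#' @param refit Refit coefficients on each test cohort (default FALSE:
#'   apply the frozen training score).
#' @param n_repeats,count_threshold,mode,cv_folds,seed Passed to
#'   [select_features()].
#' @return A list with the `selection`, the training `model`, and `results`
#'   — one row per cohort with the log-rank statistic and p-value.
#' @export
transfer_experiment <- function(train_cohort, test_cohorts = list(),
                                stable = NULL, exclude = NULL, refit = FALSE,
                                n_repeats = 20L, count_threshold = 10L,
                                mode = "train", cv_folds = 10L, seed = 1L) {
  feats <- stable %||%
    setdiff(names(train_cohort), c("subject_id", "time", "event"))
  sel <- select_features(train_cohort, feats, n_repeats = n_repeats,
                         count_threshold = count_threshold, mode = mode,
                         cv_folds = cv_folds, seed = seed)
  model <- build_score_model(sel, exclude = exclude)
  res <- list()
  if (length(model$features)) {
    res[["train"]] <- stratify_cohort(train_cohort, model)
    for (nm in names(test_cohorts)) {
      m <- if (refit) refit_score_model(model, test_cohorts[[nm]]) else model
      res[[nm]] <- stratify_cohort(test_cohorts[[nm]], m)
    }
  } else {
    empty <- tibble::tibble(n = NA_integer_, n_events = NA_integer_,
                            cutoff = NA_real_, statistic = NA_real_,
                            p_value = NA_real_, degenerate = TRUE)
    res[["train"]] <- dplyr::mutate(empty, n = nrow(train_cohort))
    for (nm in names(test_cohorts)) res[[nm]] <- empty
  }
  results <- dplyr::bind_rows(res, .id = "cohort")
  list(selection = sel, model = model, results = results)
}
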