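# ggplot2 displays for the main result types.

#' Kaplan-Meier curves by risk group
#'
#' @param groups A tibble from [median_split()] (with `time`, `event`,
#'   `risk_group`).
#' @return A ggplot object with one survival step per risk group.
#' @export
plot_km_groups <- function(groups) {
  dfs <- lapply(split(groups, groups$risk_group), function(g) {
    km <- km_estimate(g$time, g$event)
    dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                     km[, c("time", "surv")])
  })
  df <- dplyr::bind_rows(dfs, .id = "risk_group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$risk_group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  color = "Risk group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Selection-count plot
#'
#' @param object A `rad_selection`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-feature selection counts, selected
#'   features highlighted.
#' @method autoplot rad_selection
#' @export
autoplot.rad_selection <- function(object, ...) {
  df <- dplyr::filter(object$counts, .data$count > 0)
  df <- dplyr::mutate(df, feature = stats::reorder(.data$feature,
                                                   .data$count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count, y = .data$feature,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$count_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = sprintf("Selection count (of %d repeats)",
                              object$n_repeats),
                  y = NULL, fill = "Selected") +
    ggplot2::theme_minimal()
}

#' Organ histogram plot
#'
#' @param object A `rad_histogram`.
#' @param ... Unused.
#' @return A ggplot density histogram.
#' @method autoplot rad_histogram
#' @export
autoplot.rad_histogram <- function(object, ...) {
  xlab <- if (isTRUE(attr(object, "normalized"))) "Intensity (z-score)" else
    "Intensity"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin_mid, y = .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width")) +
    ggplot2::labs(x = xlab, y = "Density") +
    ggplot2::theme_minimal()
}
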