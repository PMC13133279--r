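#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Confusion-matrix heatmap for a classifier evaluation
#'
#' @param object An `rf_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(VESSEL_CLASSES)) +
    ggplot2::labs(title = sprintf("Accuracy %.1f%%", 100 * object$accuracy),
                  x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Variable-importance plot with per-class feature medians
#'
#' Mirrors the classifier diagnostic: features ordered by normalized Gini
#' importance, coloured by the median z-scored value in each vessel class
#' when a labeled feature table is supplied.
#'
#' @param eval An `rf_eval`.
#' @param labeled Optional labeled feature tibble (with `class`) used to
#'   compute per-class standardized medians.
#' @return A ggplot object.
#' @export
plot_importance <- function(eval, labeled = NULL) {
  imp <- eval$importance
  if (is.null(labeled)) {
    return(
      ggplot2::ggplot(imp, ggplot2::aes(
        x = .data$importance,
        y = stats::reorder(.data$feature, .data$importance))) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "normalized importance", y = NULL) +
        ggplot2::theme_minimal())
  }
  med <- standardize_features(labeled, class_col = "class")$class_medians
  long <- med |>
    tidyr::pivot_longer(dplyr::all_of(intersect(MORPH_FEATURES, names(med))),
                        names_to = "feature", values_to = "median_z") |>
    dplyr::left_join(imp, by = "feature")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$class,
    y = stats::reorder(.data$feature, .data$importance),
    fill = .data$median_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "median z") +
    ggplot2::theme_minimal()
}

#' Vessel-density distributions by age group
#'
#' Scatter-with-median summary of a per-case density variable across age
#' groups on a pseudo-log axis.
#'
#' @param cohort Tibble with `age_group` and the density column.
#' @param variable Density column name (default `"density_overall"`).
#' @return A ggplot object.
#' @export
plot_density_by_age <- function(cohort, variable = "density_overall") {
  df <- cohort[!is.na(cohort[[variable]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_group,
                                   y = .data[[variable]])) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.3, size = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "blue", linewidth = 0.3) +
    ggplot2::scale_y_continuous(trans = "pseudo_log") +
    ggplot2::labs(x = "age at diagnosis", y = paste(variable, "(/mm²)")) +
    ggplot2::theme_minimal()
}

#' Forest plot of age-group odds ratios
#'
#' @param analysis A `vessel_cohort_analysis`.
#' @param model Which model column to show (default "multivariable").
#' @return A ggplot object.
#' @export
plot_age_or <- function(analysis, model = "multivariable") {
  df <- tidy(analysis) |>
    dplyr::filter(.data$model == !!model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_grid(.data$stratum ~ .data$outcome) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (vs ≥70)", y = NULL) +
    ggplot2::theme_minimal()
}
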