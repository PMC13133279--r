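#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a weighted logistic fit
#'
#' One row per model term with odds ratio, robust (sandwich) 95% confidence
#' interval and p-value.
#'
#' @param x An `ipw_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (log-odds), `std.error`,
#'   `or`, `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.ipw_fit <- function(x, ...) {
  tibble::tibble(term = x$terms$term, estimate = x$terms$estimate,
                 std.error = x$terms$std_error, or = x$terms$or,
                 conf.low = x$terms$or_low, conf.high = x$terms$or_high,
                 p.value = x$terms$p)
}

#' Glance at a weighted logistic fit
#'
#' @param x An `ipw_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `p.trend`, `weighted`, `df`.
#' @export
glance.ipw_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p.trend = x$p_trend, weighted = x$weighted,
                 df = nrow(x$terms))
}

#' Tidy a classifier evaluation
#'
#' @param x An `rf_eval`.
#' @param ... Unused.
#' @return Long tibble of confusion-matrix cells: `true`, `predicted`, `n`.
#' @export
tidy.rf_eval <- function(x, ...) {
  as.data.frame(as.table(x$confusion)) |>
    stats::setNames(c("true", "predicted", "n")) |>
    tibble::as_tibble()
}

#' Glance at a classifier evaluation
#'
#' @param x An `rf_eval`.
#' @param ... Unused.
#' @return One-row tibble: `accuracy`, `n`, per-class recall columns.
#' @export
glance.rf_eval <- function(x, ...) {
  out <- tibble::tibble(accuracy = x$accuracy, n = x$n)
  for (cl in names(x$recall)) out[[paste0("recall_", cl)]] <- x$recall[[cl]]
  out
}

#' Tidy the age-association analysis into a regression table
#'
#' One row per age-group contrast, outcome, stratum and model type — the
#' odds-ratio table the analysis is run for.
#'
#' @param x A `vessel_cohort_analysis`.
#' @param ... Unused.
#' @return Tibble: `stratum`, `outcome`, `model`, `term`, `or`, `conf.low`,
#'   `conf.high`, `p.value`, `p.trend`.
#' @export
tidy.vessel_cohort_analysis <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    purrr::map_dfr(
      c(univariable = "univariable", multivariable = "multivariable",
        unweighted = "unweighted"),
      function(m) {
        tt <- tidy(f[[m]])
        tt <- tt[grepl("^age_group", tt$term), ]
        tibble::tibble(stratum = f$stratum, outcome = f$outcome, model = m,
                       term = sub("^age_group", "age ", tt$term),
                       or = tt$or, conf.low = tt$conf.low,
                       conf.high = tt$conf.high, p.value = tt$p.value,
                       p.trend = f[[m]]$p_trend)
      })
  })
}

#' Glance at the age-association analysis
#'
#' @param x A `vessel_cohort_analysis`.
#' @param ... Unused.
#' @return One-row tibble: cohort sizes, weight range, significant trends.
#' @export
glance.vessel_cohort_analysis <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_available = x$n_available,
                 max_weight = max(x$weights$weight),
                 n_significant_trends = sum(x$trend$significant,
                                            na.rm = TRUE))
}
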