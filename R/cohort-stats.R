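#' Statistical analysis configuration
#'
#' @param alpha Two-sided significance level after multiplicity adjustment
#'   for the nine vessel variables (default 0.005, about 0.05/9).
#' @param elimination_threshold Backward-elimination p-value threshold
#'   (default 0.1).
#' @param weight_truncation Quantile at which IPW weights are truncated
#'   (default 0.99).
#' @param forced_terms Model terms never removed by elimination (default
#'   `"age_group"`).
#' @param covariates Initial multivariable covariate set.
#' @param availability_predictors Predictors of the tissue-availability
#'   model.
#' @param scheme Dichotomization scheme passed to [dichotomize()]; `NULL`
#'   uses the median-based default rules.
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.005,
                         elimination_threshold = 0.1,
                         weight_truncation = 0.99,
                         forced_terms = "age_group",
                         covariates = c("sex", "bmi30", "smoking_cat",
                                        "famhx", "location", "msi", "cimp",
                                        "line1", "kras", "braf", "pik3ca"),
                         availability_predictors = c("age_group", "sex",
                                                     "stage", "year_dx"),
                         scheme = NULL) {
  stopifnot(alpha > 0, alpha < 1,
            elimination_threshold > 0, elimination_threshold < 1)
  structure(list(alpha = alpha,
                 elimination_threshold = elimination_threshold,
                 weight_truncation = weight_truncation,
                 forced_terms = forced_terms, covariates = covariates,
                 availability_predictors = availability_predictors,
                 scheme = scheme),
            class = "stats_config")
}

#' Pool per-core vessel metrics into per-case metrics
#'
#' Pooled density = sum of category counts across a case's QC-passing cores
#' divided by the summed core areas (robust to unequal core tissue areas and
#' invariant to core order). Cases whose cores all failed QC are dropped and
#' listed in the `dropped_cases` attribute.
#'
#' @param cores Tibble with one row per core: `case_id`, `core_area_mm2`,
#'   `count_*` columns, and optionally `qc_pass`.
#' @return Tibble with one row per case: `case_id`, `n_cores`, and
#'   `density_*` columns (vessels/mm^2).
#' @export
aggregate_case_metrics <- function(cores) {
  stopifnot(is.data.frame(cores),
            all(c("case_id", "core_area_mm2") %in% names(cores)))
  if ("qc_pass" %in% names(cores)) {
    all_cases <- unique(cores$case_id)
    cores <- dplyr::filter(cores, .data$qc_pass)
    dropped <- setdiff(all_cases, unique(cores$case_id))
  } else {
    dropped <- character()
  }
  count_cols <- grep("^count_", names(cores), value = TRUE)
  out <- cores |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      total_area_mm2 = sum(.data$core_area_mm2),
      dplyr::across(dplyr::all_of(count_cols), sum),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(count_cols),
      ~ ifelse(.data$total_area_mm2 > 0, .x / .data$total_area_mm2, NA_real_),
      .names = "{sub('count_', 'density_', .col)}")) |>
    dplyr::select(-dplyr::all_of(count_cols))
  structure(out, dropped_cases = dropped)
}

#' Dichotomize vessel-density variables
#'
#' The default scheme follows the analysis rules: overall and micro density
#' split at their cohort medians; LAMB1 split into high (strictly above the
#' median among cases with non-zero values) versus low/negative, with zeros
#' always low. "Above" is strict everywhere, so the median-valued case goes
#' low. Rules may alternatively be fixed numeric cutpoints.
#'
#' @param metrics Data frame with density columns.
#' @param scheme Named list; each element is
#'   `list(var = <column>, rule = "median"|"nonzero_median"|<numeric>)`.
#' @return `metrics` with one `high_<name>` 0/1 column per scheme element;
#'   cutpoints used are in `attr(, "cutpoints")`.
#' @export
dichotomize <- function(metrics, scheme = NULL) {
  stopifnot(is.data.frame(metrics))
  if (is.null(scheme)) {
    scheme <- list(
      overall = list(var = "density_overall", rule = "median"),
      micro = list(var = "density_micro", rule = "median"),
      lamb1 = list(var = "density_LAMB1", rule = "nonzero_median"))
  }
  if (nrow(metrics) < 2L) stop("need at least two cases to dichotomize")
  cutpoints <- numeric(0)
  for (nm in names(scheme)) {
    sp <- scheme[[nm]]
    x <- metrics[[sp$var]]
    cut <- if (is.numeric(sp$rule)) {
      sp$rule
    } else if (sp$rule == "median") {
      stats::median(x, na.rm = TRUE)
    } else if (sp$rule == "nonzero_median") {
      stats::median(x[!is.na(x) & x > 0])
    } else {
      stop("unknown dichotomization rule: ", sp$rule)
    }
    vals <- x[!is.na(x)]
    if (length(unique(vals)) == 1L) {
      warning("all '", sp$var, "' values equal; every case classified low")
    }
    metrics[[paste0("high_", nm)]] <- as.integer(x > cut)
    cutpoints[nm] <- cut
  }
  structure(metrics, cutpoints = cutpoints)
}

#' Spearman rank-correlation trend test
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric (or ordinal-coded) vectors; pairs with missing values
#'   are dropped.
#' @return One-row tibble: `rho`, `p`, `n`, `flag` (set for degenerate
#'   constant input, where rho is undefined).
#' @export
spearman_trend <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n,
                          flag = "constant input"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n, flag = NA_character_)
}

#' Estimate inverse-probability-of-availability weights
#'
#' Fits a logistic model of tissue availability on the configured predictors
#' over the *full* cohort (available and unavailable cases); available cases
#' receive weight 1 / fitted probability, truncated at the configured upper
#' quantile. A covariate balance diagnostic (weighted standardized mean
#' differences of the model predictors, available cases vs full cohort) is
#' attached.
#'
#' @param cohort Full-cohort tibble with a logical `tissue_available` column.
#' @param predictors Predictor column names.
#' @param truncate_at Upper weight-quantile truncation bound (default 0.99;
#'   `NULL` disables truncation).
#' @return Tibble `case_id`, `p_available`, `weight` (rows = available
#'   cases), with `attr(, "balance")` and `attr(, "model")`.
#' @export
estimate_ipw_weights <- function(cohort,
                                 predictors = c("age_group", "sex", "stage",
                                                "year_dx"),
                                 truncate_at = 0.99) {
  stopifnot("tissue_available" %in% names(cohort),
            all(predictors %in% names(cohort)))
  if (all(cohort$tissue_available) ) {
    w <- tibble::tibble(case_id = cohort$case_id,
                        p_available = 1, weight = 1)
    return(structure(w[cohort$tissue_available, ], balance = NULL,
                     model = NULL))
  }
  f <- stats::reformulate(predictors, response = "tissue_available")
  fit <- stats::glm(f, family = stats::binomial(), data = cohort)
  p <- stats::fitted(fit)
  if (any(p < 1e-8) || any(p > 1 - 1e-8) || !fit$converged) {
    stop("separation or non-convergence in the availability model; ",
         "fitted probabilities span [", format(min(p)), ", ",
         format(max(p)), "]")
  }
  av <- cohort$tissue_available
  w <- 1 / p[av]
  if (!is.null(truncate_at)) {
    w <- pmin(w, stats::quantile(w, truncate_at))
  }
  out <- tibble::tibble(case_id = cohort$case_id[av],
                        p_available = p[av], weight = unname(w))
  structure(out, balance = ipw_balance(cohort, av, w, predictors),
            model = fit)
}

# weighted standardized mean differences of the availability predictors
# (weighted available sample vs full cohort), numeric-coded per level
ipw_balance <- function(cohort, av, w, predictors) {
  purrr::map_dfr(predictors, function(v) {
    x <- cohort[[v]]
    cols <- if (is.numeric(x)) {
      stats::setNames(list(x), v)
    } else {
      lv <- sort(unique(as.character(x)))
      stats::setNames(lapply(lv, function(l) as.numeric(x == l)),
                      paste0(v, "=", lv))
    }
    purrr::map_dfr(names(cols), function(nm) {
      z <- cols[[nm]]
      full_mean <- mean(z)
      wt_mean <- sum(w * z[av]) / sum(w)
      s <- stats::sd(z)
      tibble::tibble(term = nm, full_mean = full_mean,
                     weighted_mean = wt_mean,
                     smd = if (s > 0) abs(wt_mean - full_mean) / s else 0)
    })
  })
}

#' Weighted logistic regression with robust variance
#'
#' Weighted maximum-likelihood logistic fit (via `glm`, quasibinomial link so
#' non-integer IPW weights are handled) with a sandwich (HC0) variance
#' estimator — model-based variance understates uncertainty when weights are
#' estimated. Odds ratios are exponentiated coefficients with Wald 95%
#' confidence intervals. When `trend_term` is supplied, a companion model
#' with that continuous term substituted for `age_group` provides `p_trend`.
#'
#' @param data Model-ready tibble.
#' @param outcome Name of the 0/1 outcome column.
#' @param terms Character vector of predictor terms.
#' @param weights Positive case weights (default all 1).
#' @param trend_term Continuous column substituted for `age_group` in the
#'   trend model (default `"age"`; `NULL` skips the trend test).
#' @param on_separation `"error"` (default) fails on detected
#'   (quasi-)separation; `"warn"` downgrades it to a warning so callers such
#'   as [backward_eliminate()] can drop the offending term instead.
#' @return Object of class `ipw_fit`.
#' @export
fit_weighted_logistic <- function(data, outcome, terms, weights = NULL,
                                  trend_term = "age",
                                  on_separation = c("error", "warn")) {
  on_separation <- match.arg(on_separation)
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data), all(weights > 0))
  data <- dplyr::mutate(data, .w = weights)
  f <- stats::reformulate(terms, response = outcome)
  fit <- stats::glm(f, family = stats::quasibinomial(), data = data,
                    weights = .w)
  if (!fit$converged) stop("weighted logistic fit did not converge")
  p_hat <- stats::fitted(fit)
  if (any(p_hat < 1e-10) || any(p_hat > 1 - 1e-10)) {
    msg <- paste0("separation detected in weighted logistic fit for ",
                  "outcome '", outcome, "'")
    if (on_separation == "error") stop(msg) else warning(msg)
  }
  V <- robust_vcov(fit)
  b <- stats::coef(fit)
  b <- b[!is.na(b)]            # aliased (collinear) columns are dropped
  b <- b[rownames(V)]
  se <- sqrt(diag(V))
  z <- b / se
  terms_tbl <- tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    or = exp(unname(b)),
    or_low = exp(unname(b - 1.96 * se)),
    or_high = exp(unname(b + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(unname(z))))
  p_trend <- NA_real_
  if (!is.null(trend_term) && "age_group" %in% terms &&
      trend_term %in% names(data)) {
    tterms <- c(trend_term, setdiff(terms, "age_group"))
    tf <- stats::reformulate(tterms, response = outcome)
    tfit <- stats::glm(tf, family = stats::quasibinomial(), data = data,
                       weights = .w)
    tV <- robust_vcov(tfit)
    tb <- stats::coef(tfit)[trend_term]
    tse <- sqrt(tV[trend_term, trend_term])
    p_trend <- 2 * stats::pnorm(-abs(tb / tse))
  }
  structure(list(model = fit, vcov = V, terms = terms_tbl,
                 outcome = outcome, formula = f, p_trend = unname(p_trend),
                 weighted = !all(weights == weights[1]) || weights[1] != 1,
                 n = nrow(data)),
            class = "ipw_fit")
}

#' @export
print.ipw_fit <- function(x, ...) {
  cat("<ipw_fit> ", x$outcome, " ~ ", deparse(x$formula[[3]]),
      "  (n = ", x$n, if (x$weighted) ", IPW-weighted" else "",
      ")\n", sep = "")
  print(x$terms, n = Inf)
  if (!is.na(x$p_trend)) cat("p_trend (continuous age):",
                             format.pval(x$p_trend), "\n")
  invisible(x)
}

# HC0 sandwich covariance. Near-singleton cells (e.g. a missing-indicator
# matched by one case) give hat values ~1; sandwich warns per fit, but the
# affected block tests are guarded downstream, so the repeated diagnostic
# is muffled here.
robust_vcov <- function(fit) {
  withCallingHandlers(
    sandwich::vcovHC(fit, type = "HC0"),
    warning = function(w) {
      if (grepl("hat values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# largest absolute coefficient per model term (divergence diagnostic)
block_coef_max <- function(fit_obj) {
  fit <- fit_obj$model
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  cn <- colnames(mm)
  b <- stats::coef(fit)
  vapply(seq_along(labels), function(i) {
    bi <- b[cn[asgn == i]]
    bi <- bi[!is.na(bi)]
    if (length(bi) == 0L) 0 else max(abs(bi))
  }, numeric(1)) |> stats::setNames(labels)
}

# robust joint Wald test for all coefficients belonging to one model term
block_wald_p <- function(fit_obj) {
  fit <- fit_obj$model
  V <- fit_obj$vcov
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  cn <- colnames(mm)
  bfull <- stats::coef(fit)
  vapply(seq_along(labels), function(i) {
    nms <- cn[asgn == i]
    nms <- nms[nms %in% rownames(V) & !is.na(bfull[nms])]
    if (length(nms) == 0L) return(NA_real_)
    b <- bfull[nms]
    W <- tryCatch(drop(t(b) %*% solve(V[nms, nms, drop = FALSE], b)),
                  error = function(e) NA_real_)
    stats::pchisq(W, df = length(b), lower.tail = FALSE)
  }, numeric(1)) |> stats::setNames(labels)
}

#' Backward elimination with forced-in terms
#'
#' Iteratively removes the non-forced term with the largest joint Wald
#' p-value at or above the threshold, refitting after each removal, until
#' every remaining non-forced term has p below the threshold. Multi-level
#' covariates enter and leave as whole blocks. Forced terms (age by default)
#' are never removed. Non-forced terms whose coefficient block diverges
#' (quasi-separation, e.g. a near-singleton missing-indicator cell perfectly
#' predicted) are dropped first, mirroring how degenerate covariates are
#' handled in practice; separation surviving to the final model is an error.
#' The full elimination path is recorded.
#'
#' @param data,outcome,weights As in [fit_weighted_logistic()].
#' @param terms Initial model terms.
#' @param threshold Removal threshold (default 0.1).
#' @param forced Terms never removed.
#' @return The final `ipw_fit`, with `attr(, "path")`, a tibble of the
#'   removal sequence.
#' @export
backward_eliminate <- function(data, outcome, terms, weights = NULL,
                               threshold = 0.1, forced = "age_group") {
  current <- terms
  path <- list()
  note <- function(term, p, reason) {
    path[[length(path) + 1L]] <<-
      tibble::tibble(step = length(path) + 1L, removed = term,
                     p = p, reason = reason)
  }
  repeat {
    fit <- suppressWarnings(
      fit_weighted_logistic(data, outcome, current, weights,
                            on_separation = "warn"))
    # degenerate (diverging) non-forced blocks are dropped before p-based
    # elimination
    bmax <- block_coef_max(fit)
    degen <- setdiff(names(bmax)[bmax > 10], forced)
    if (length(degen) > 0L) {
      note(degen[1L], NA_real_, "separation")
      current <- setdiff(current, degen[1L])
      next
    }
    p <- block_wald_p(fit)
    candidates <- p[setdiff(names(p), forced)]
    if (length(candidates) == 0L || all(candidates < threshold, na.rm = TRUE)) {
      break
    }
    drop_term <- names(candidates)[which.max(candidates)]
    note(drop_term, unname(candidates[drop_term]), "p >= threshold")
    current <- setdiff(current, drop_term)
  }
  # refit the final model with the strict separation contract
  fit <- fit_weighted_logistic(data, outcome, current, weights)
  structure(fit, path = dplyr::bind_rows(path), final_terms = current)
}

#' Prepare a model-ready table under the missing-data conventions
#'
#' Categorical covariates with missing values are assigned to the majority
#' category, with a 0/1 missing-indicator column added per affected
#' covariate (limits model degrees of freedom). LINE-1 methylation is the
#' exception: its missing cases become a separate `"missing"` level rather
#' than being imputed. Derived modeling covariates (`bmi30`, `smoking_cat`)
#' are added when their sources are present.
#'
#' @param cohort Cohort tibble.
#' @param impute_vars Categorical covariates under the majority-category
#'   rule.
#' @param line1_var Covariate under the separate-indicator rule.
#' @return Model-ready tibble; indicator columns are named `<var>_missing`.
#' @export
handle_missing <- function(cohort,
                           impute_vars = c("famhx", "location", "msi",
                                           "cimp", "kras", "braf", "pik3ca"),
                           line1_var = "line1") {
  out <- cohort
  if ("bmi" %in% names(out) && !"bmi30" %in% names(out)) {
    out$bmi30 <- ifelse(out$bmi >= 30, ">=30", "<30")
  }
  if ("pack_years" %in% names(out) && !"smoking_cat" %in% names(out)) {
    out$smoking_cat <- cut(out$pack_years, c(-Inf, 0, 39, Inf),
                           labels = c("0", "1-39", ">=40"))
  }
  for (v in intersect(impute_vars, names(out))) {
    x <- out[[v]]
    miss <- is.na(x)
    if (any(miss)) {
      majority <- names(sort(table(x), decreasing = TRUE))[1L]
      x[miss] <- majority
      out[[v]] <- x
      out[[paste0(v, "_missing")]] <- as.integer(miss)
    }
  }
  if (line1_var %in% names(out)) {
    x <- out[[line1_var]]
    if (any(is.na(x))) {
      x[is.na(x)] <- "missing"
      out[[line1_var]] <- x
    }
  }
  out
}

#' Multiplicity flags for the nine vessel variables
#'
#' @param p Numeric vector of nine p-values (one per vessel variable).
#' @param alpha Adjusted two-sided alpha (default 0.005, about 0.05/9).
#' @return Tibble `p`, `significant` (strictly below alpha).
#' @export
multiplicity_flag <- function(p, alpha = 0.005) {
  stopifnot(is.numeric(p))
  tibble::tibble(p = p, significant = !is.na(p) & p < alpha)
}

#' Run the full age-vessel association analysis
#'
#' End-to-end orchestration: missing-data handling, IPW weight estimation
#' from the full cohort, outcome dichotomization, and — for each outcome
#' (overall, micro, LAMB1) in each stratum (all cases, non-MSI-high) —
#' univariable IPW, multivariable IPW with backward elimination, and an
#' unweighted multivariable sensitivity fit. A Spearman age-trend table over
#' the nine density variables (with multiplicity flags) and age-by-outcome
#' cross-tabulations are included.
#'
#' @param cohort Full-cohort tibble from [generate_cohort()] (or a real
#'   cohort with the same columns).
#' @param metrics Optional per-case metrics from [aggregate_case_metrics()],
#'   joined on `case_id`; by default density columns already present in
#'   `cohort` are used.
#' @param config A [stats_config()].
#' @return Object of class `vessel_cohort_analysis`.
#' @export
run_full_analysis <- function(cohort, metrics = NULL,
                              config = stats_config()) {
  stopifnot(is.data.frame(cohort), inherits(config, "stats_config"))
  if (!is.null(metrics)) {
    dens_cols <- grep("^density_", names(metrics), value = TRUE)
    cohort <- cohort |>
      dplyr::select(-dplyr::any_of(dens_cols)) |>
      dplyr::left_join(metrics[, c("case_id", dens_cols)], by = "case_id")
  }
  cohort <- handle_missing(cohort)
  wts <- estimate_ipw_weights(cohort, config$availability_predictors,
                              config$weight_truncation)
  avail <- cohort |>
    dplyr::filter(.data$tissue_available) |>
    dplyr::left_join(wts[, c("case_id", "weight")], by = "case_id")
  avail <- dichotomize(avail, config$scheme)
  outcomes <- grep("^high_", names(avail), value = TRUE)

  density_cols <- c("density_overall", "density_collapsed", "density_micro",
                    "density_patent", "density_ACKR1", "density_CD36",
                    "density_KDR", "density_LAMB1", "density_MADCAM1")
  density_cols <- intersect(density_cols, names(avail))
  trend <- purrr::map_dfr(density_cols, function(v) {
    st <- spearman_trend(avail$age, avail[[v]])
    dplyr::mutate(st, variable = v, .before = 1L)
  })
  trend$significant <- multiplicity_flag(trend$p, config$alpha)$significant

  strata <- list(all = rep(TRUE, nrow(avail)),
                 `non-MSI-high` = avail$msi == "non-MSI-high")
  fits <- list()
  for (snm in names(strata)) {
    sub <- avail[strata[[snm]], ]
    covs <- config$covariates
    if (snm == "non-MSI-high") covs <- setdiff(covs, "msi")
    covs <- intersect(c(covs, paste0(covs, "_missing")), names(sub))
    covs <- covs[vapply(covs, function(v) length(unique(sub[[v]])) > 1L,
                        logical(1))]
    for (out in outcomes) {
      uni <- fit_weighted_logistic(sub, out, "age_group", sub$weight)
      multi <- backward_eliminate(sub, out, c("age_group", covs),
                                  sub$weight,
                                  threshold = config$elimination_threshold,
                                  forced = config$forced_terms)
      unwt <- backward_eliminate(sub, out, c("age_group", covs),
                                 weights = NULL,
                                 threshold = config$elimination_threshold,
                                 forced = config$forced_terms)
      fits[[paste(snm, out, sep = ".")]] <-
        list(stratum = snm, outcome = out, univariable = uni,
             multivariable = multi, unweighted = unwt)
    }
  }
  xtab <- lapply(stats::setNames(outcomes, outcomes), function(out) {
    table(age = avail$age_group, outcome = avail[[out]])
  })
  structure(list(fits = fits, trend = trend, crosstab = xtab,
                 weights = wts, n_total = nrow(cohort),
                 n_available = nrow(avail), config = config),
            class = "vessel_cohort_analysis")
}

#' @export
print.vessel_cohort_analysis <- function(x, ...) {
  cat("<vessel_cohort_analysis> ", x$n_available, " available of ",
      x$n_total, " cases; ", length(x$fits), " model sets\n", sep = "")
  cat("Age-trend (Spearman) summary:\n")
  print(x$trend, n = Inf)
  invisible(x)
}
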