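test_that("per-case pooling is count-over-area and order invariant", {
  cores <- tibble::tibble(
    case_id = c("a", "b", "b"), core_id = c("c1", "c2", "c3"),
    core_area_mm2 = c(0.5, 0.3, 0.3),
    count_overall = c(20, 10, 20), count_micro = c(10, 5, 10),
    qc_pass = TRUE)
  m <- aggregate_case_metrics(cores)
  expect_equal(m$density_overall[m$case_id == "a"], 40)   # one core: as-is
  expect_equal(m$density_overall[m$case_id == "b"], 50)   # 30 / 0.6
  expect_equal(m$n_cores, c(1L, 2L))
  m2 <- aggregate_case_metrics(cores[c(3, 1, 2), ])
  expect_equal(as.data.frame(m2), as.data.frame(m))
  # all-failed cases are dropped and recorded
  cores$qc_pass <- c(FALSE, TRUE, TRUE)
  m3 <- aggregate_case_metrics(cores)
  expect_false("a" %in% m3$case_id)
  expect_equal(attr(m3, "dropped_cases"), "a")
})

test_that("dichotomization rules are strict and handle the LAMB1 convention", {
  tb <- tibble::tibble(density_overall = c(1, 2, 3, 4),
                       density_micro = c(1, 1, 2, 2),
                       density_LAMB1 = c(0, 0, 2, 4))
  tb <- rbind(tb, tibble::tibble(density_overall = 2.5, density_micro = 1.5,
                                 density_LAMB1 = 6))
  d <- dichotomize(tb)
  # overall median 2.5 -> {3, 4} high, the median-valued case goes low
  expect_equal(d$high_overall, c(0L, 0L, 1L, 1L, 0L))
  # LAMB1 non-zero median of (2, 4, 6) = 4 -> only 6 is high; zeros low
  expect_equal(d$high_lamb1, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(sum(d$high_overall) + sum(d$high_overall == 0), nrow(tb))
  # shift invariance of the median split
  d2 <- dichotomize(dplyr::mutate(tb, density_overall = density_overall + 100),
                    scheme = list(overall = list(var = "density_overall",
                                                 rule = "median")))
  expect_equal(d2$high_overall, d$high_overall)
  # degenerate all-equal input
  expect_warning(
    dall <- dichotomize(tibble::tibble(density_overall = c(2, 2, 2)),
                        scheme = list(o = list(var = "density_overall",
                                               rule = "median"))),
    "all")
  expect_equal(dall$high_o, c(0L, 0L, 0L))
})

test_that("Spearman trend matches hand computation and the rank oracle", {
  st <- spearman_trend(c(40, 50, 60, 70, 80), 1:5)
  expect_equal(st$rho, 1)
  st2 <- spearman_trend(c(40, 50, 60, 70, 75), c(1, 1, 2, 2, 2))
  expect_equal(st2$rho, slow_spearman(c(40, 50, 60, 70, 75), c(1, 1, 2, 2, 2)))
  # the documented 4-point tie case: rho = 4 / sqrt(20)
  expect_equal(slow_spearman(c(40, 50, 60, 70), c(1, 1, 2, 2)), 4 / sqrt(20))
  set.seed(40)
  for (i in 1:100) {
    x <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- sample(1:5, 30, replace = TRUE)
    expect_equal(spearman_trend(x, y)$rho, slow_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_trend(x, y)$rho, spearman_trend(y, x)$rho)
  }
  expect_error(spearman_trend(1:3, 1:3), "at least 5")
  flagged <- spearman_trend(rep(1, 10), 1:10)
  expect_true(is.na(flagged$rho))
  expect_equal(flagged$flag, "constant input")
})

test_that("IPW weights invert availability probabilities exactly in strata", {
  # two strata with availability 0.5 and 1 - eps
  set.seed(3)
  n <- 4000
  coh <- tibble::tibble(
    case_id = as.character(1:n),
    age_group = factor(rep(AGE_GROUPS[1:2], each = n / 2),
                       levels = AGE_GROUPS))
  p <- ifelse(coh$age_group == AGE_GROUPS[1], 0.5, 0.95)
  coh$tissue_available <- runif(n) < p
  w <- estimate_ipw_weights(coh, predictors = "age_group",
                            truncate_at = NULL)
  # saturated model: weighted stratum totals equal full-cohort totals
  joined <- dplyr::left_join(coh, w, by = "case_id") |>
    dplyr::filter(tissue_available)
  tot <- joined |>
    dplyr::group_by(age_group) |>
    dplyr::summarise(wsum = sum(weight))
  expect_equal(tot$wsum, c(n / 2, n / 2), tolerance = 1e-9)
  bal <- attr(w, "balance")
  expect_true(all(bal$smd < 1e-9))
  # availability 1 for everyone -> unit weights
  coh$tissue_available <- TRUE
  w1 <- estimate_ipw_weights(coh, predictors = "age_group")
  expect_true(all(w1$weight == 1))
})

test_that("IPW achieves covariate balance on the simulated cohort", {
  coh <- generate_cohort(cohort_sim_config(seed = 314))
  w <- estimate_ipw_weights(coh)
  bal <- attr(w, "balance")
  expect_true(all(bal$smd < 0.05))
  expect_true(all(w$weight >= 1))
})

test_that("weighted logistic fit reproduces the saturated 2x2 odds ratio", {
  df <- tibble::tibble(
    exposed = rep(c(1, 0), c(50, 100)),
    high = c(rep(1, 10), rep(0, 40), rep(1, 50), rep(0, 50)))
  fit <- fit_weighted_logistic(df, "high", "exposed", trend_term = NULL)
  expect_equal(tidy(fit)$or[2], 0.25, tolerance = 1e-8)
  # doubling all weights leaves point estimates unchanged
  fit2 <- fit_weighted_logistic(df, "high", "exposed",
                                weights = rep(2, nrow(df)),
                                trend_term = NULL)
  expect_equal(coef(fit2$model), coef(fit$model), tolerance = 1e-6)
  # CI brackets the OR
  td <- tidy(fit)
  expect_true(all(td$conf.low <= td$or & td$or <= td$conf.high))
})

test_that("null simulation gives odds ratios near 1 and uniform p_trend", {
  set.seed(99)
  ors <- c(); ps <- c()
  for (i in 1:30) {
    n <- 600
    df <- tibble::tibble(
      age = runif(n, 45, 85),
      high = rbinom(n, 1, 0.5))
    df$age_group <- cut(df$age, c(-Inf, 55, 70, Inf),
                        labels = rev(AGE_GROUPS), right = FALSE)
    df$age_group <- factor(df$age_group, levels = AGE_GROUPS)
    fit <- fit_weighted_logistic(df, "high", "age_group")
    ors <- c(ors, tidy(fit)$or[2])
    ps <- c(ps, fit$p_trend)
  }
  expect_equal(exp(mean(log(ors))), 1, tolerance = 0.1)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("backward elimination keeps forced age, drops noise, keeps signal", {
  set.seed(123)
  n <- 5000
  df <- tibble::tibble(
    age = runif(n, 45, 85),
    noise = factor(sample(c("x", "y"), n, TRUE)),
    strong = rbinom(n, 1, 0.5))
  df$age_group <- factor(cut(df$age, c(-Inf, 55, 70, Inf),
                             labels = rev(AGE_GROUPS), right = FALSE),
                         levels = AGE_GROUPS)
  lin <- -0.1 + log(2) * df$strong
  df$high <- rbinom(n, 1, plogis(lin))
  fit <- backward_eliminate(df, "high", c("age_group", "noise", "strong"))
  final <- attr(fit, "final_terms")
  expect_true("age_group" %in% final)     # forced in, though unrelated
  expect_true("strong" %in% final)        # planted OR 2 retained
  path <- attr(fit, "path")
  expect_true(nrow(path) == 0 || all(path$p >= 0.1))
})

test_that("pure-noise covariates are eliminated in most replicates", {
  set.seed(456)
  kept <- 0L
  for (i in 1:20) {
    n <- 2000
    df <- tibble::tibble(
      age = runif(n, 45, 85),
      noise = factor(sample(c("x", "y", "z"), n, TRUE)),
      high = rbinom(n, 1, 0.5))
    df$age_group <- factor(cut(df$age, c(-Inf, 55, 70, Inf),
                               labels = rev(AGE_GROUPS), right = FALSE),
                           levels = AGE_GROUPS)
    fit <- backward_eliminate(df, "high", c("age_group", "noise"))
    if ("noise" %in% attr(fit, "final_terms")) kept <- kept + 1L
  }
  expect_lte(kept / 20, 0.35)   # nominal retention rate is the 0.1 threshold
})

test_that("missing-data conventions: majority imputation plus indicators", {
  tb <- tibble::tibble(
    cimp = c(rep("negative/low", 60), rep("high", 40), rep(NA, 5)),
    line1 = c(rep("55-65", 100), rep(NA, 5)),
    msi = rep("non-MSI-high", 105))
  out <- handle_missing(tb)
  expect_equal(sum(out$cimp == "negative/low"), 65)   # majority level
  expect_equal(sum(out$cimp_missing), 5)
  expect_true(all(out$cimp_missing %in% 0:1))
  # LINE-1: separate level, no imputation
  expect_equal(sum(out$line1 == "missing"), 5)
  expect_false("line1_missing" %in% names(out))
  # untouched table stays untouched
  clean <- tibble::tibble(msi = rep("non-MSI-high", 10))
  expect_identical(handle_missing(clean), clean)
})

test_that("multiplicity flags use the adjusted alpha strictly", {
  flags <- multiplicity_flag(c(0.012, 0.0030, 0.005, rep(1, 6)))
  expect_false(flags$significant[1])   # 0.012 is not significant at 0.005
  expect_true(flags$significant[2])    # 0.0030 is
  expect_false(flags$significant[3])   # boundary: strict <
  expect_false(any(flags$significant[4:9]))
})

test_that("full analysis emits the whole report structure", {
  coh <- generate_cohort(cohort_sim_config(seed = 2718))
  res <- run_full_analysis(coh)
  expect_s3_class(res, "vessel_cohort_analysis")
  expect_length(res$fits, 6)   # 3 outcomes x 2 strata
  for (f in res$fits) {
    expect_s3_class(f$univariable, "ipw_fit")
    expect_s3_class(f$multivariable, "ipw_fit")
    expect_s3_class(f$unweighted, "ipw_fit")
    expect_true("age_group" %in% attr(f$multivariable, "final_terms"))
  }
  expect_equal(nrow(res$trend), 9)
  td <- tidy(res)
  expect_equal(nrow(td), 6 * 3 * 2)    # 2 age contrasts per model
  expect_true(all(td$or > 0))
  gl <- glance(res)
  expect_equal(gl$n_total, 4476)
  # with all-available cohort, weighted and unweighted paths coincide
  coh2 <- coh
  coh2$tissue_available <- TRUE
  dens <- grep("^density_", names(coh2), value = TRUE)
  for (v in dens) coh2[[v]][is.na(coh2[[v]])] <- median(coh2[[v]], na.rm = TRUE)
  coh2$n_cores[is.na(coh2$n_cores)] <- 1L
  res2 <- run_full_analysis(coh2)
  f <- res2$fits[["all.high_overall"]]
  expect_equal(coef(f$multivariable$model), coef(f$unweighted$model),
               tolerance = 1e-8)
})
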