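#' Age-group labels used throughout (referent first)
#' @export
AGE_GROUPS <- c(">=70", "55-69", "<55")

#' Cohort simulator configuration
#'
#' Defines the study conditions of the simulated incident-cancer cohort: a
#' full cohort of `n_total` cases of which a minority have tumor-tissue assay
#' data, with tissue availability depending on age group, sex, stage and
#' diagnosis year, and per-case vessel densities whose high/low states are
#' planted per age group.
#'
#' The default planted high-density probabilities per age group
#' (<55 / 55-69 / >=70) encode the planted age-density odds ratios vs the
#' >=70 referent: overall 0.386/0.459/0.500 (ORs 0.63 / 0.85),
#' LAMB1 0.219/0.359/0.500 (ORs 0.28 / 0.56), micro 0.537/0.457/0.500
#' (ORs 1.16 / 0.84).
#'
#' @param n_total Total incident cases (default 4476).
#' @param n_by_age Expected counts of *available* cases by age group
#'   <55 / 55-69 / >=70 (defaults 52 / 400 / 391, summing to 843).
#' @param age_mix Full-cohort age-group proportions (<55 / 55-69 / >=70).
#' @param p_high_by_age Named list of per-outcome c(lt55, a5569, ge70)
#'   probabilities of the "high" density state.
#' @param availability_model Coefficients of the logistic
#'   tissue-availability model: `sex_male`, `stage_high` (stage III/IV),
#'   `year` (per year from 2000); age-group intercepts are calibrated
#'   internally so the expected available counts match `n_by_age`.
#' @param missing_rates Named per-covariate missingness probabilities.
#' @param cutpoints Fixed density cutpoints that separate the planted low and
#'   high continuous values (vessels/mm^2): overall 197, micro 93, and the
#'   LAMB1 nonzero split 8.
#' @param seed Optional RNG seed (`NULL` uses the current RNG state).
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_total = 4476L,
    n_by_age = c(lt55 = 52, a5569 = 400, ge70 = 391),
    age_mix = c(lt55 = 0.08, a5569 = 0.47, ge70 = 0.45),
    p_high_by_age = list(
      overall = c(lt55 = 0.386, a5569 = 0.459, ge70 = 0.500),
      micro   = c(lt55 = 0.537, a5569 = 0.457, ge70 = 0.500),
      lamb1   = c(lt55 = 0.219, a5569 = 0.359, ge70 = 0.500)),
    availability_model = c(sex_male = 0.2, stage_high = -0.15, year = -0.01),
    missing_rates = c(famhx = 0.005, location = 0.004, msi = 0.031,
                      cimp = 0.076, kras = 0.030, braf = 0.023,
                      pik3ca = 0.088, line1 = 0.029),
    cutpoints = c(overall = 197, micro = 93, lamb1 = 8),
    seed = NULL) {
  stopifnot(n_total > 0, all(n_by_age > 0), abs(sum(age_mix) - 1) < 1e-9)
  for (p in p_high_by_age) {
    if (any(p < 0 | p > 1)) stop("p_high_by_age probabilities must be in [0,1]")
  }
  if (any(missing_rates < 0 | missing_rates > 1)) {
    stop("missing_rates must be in [0,1]")
  }
  cfg <- list(n_total = as.integer(n_total), n_by_age = n_by_age,
              age_mix = age_mix, p_high_by_age = p_high_by_age,
              availability_model = availability_model,
              missing_rates = missing_rates, cutpoints = cutpoints,
              seed = seed)
  cfg$age_intercepts <- calibrate_availability(cfg)
  structure(cfg, class = "cohort_sim_config")
}

# per-age-group covariate marginals used by the generator (age-structured
# where the cohort literature shows structure, constant otherwise)
cohort_marginals <- function() {
  list(
    sex_male = c(lt55 = 0.23, a5569 = 0.38, ge70 = 0.54),
    stage = rbind(lt55 = c(0.22, 0.20, 0.44, 0.14),
                  a5569 = c(0.20, 0.33, 0.29, 0.18),
                  ge70 = c(0.27, 0.34, 0.26, 0.13)),
    location = rbind(lt55 = c(0.37, 0.40, 0.23),
                     a5569 = c(0.46, 0.33, 0.21),
                     ge70 = c(0.56, 0.24, 0.20)),
    msi_high = c(lt55 = 0.10, a5569 = 0.16, ge70 = 0.20),
    cimp_high = c(lt55 = 0.10, a5569 = 0.15, ge70 = 0.24),
    line1 = rbind(lt55 = c(0.26, 0.41, 0.33),
                  a5569 = c(0.22, 0.42, 0.36),
                  ge70 = c(0.20, 0.37, 0.43)),
    kras_mut = 0.40, braf_mut = 0.16, pik3ca_mut = 0.17,
    famhx_present = 0.21, years = 1988:2012)
}

# solve per-age-group intercepts of the availability logit so the expected
# available count in each group equals n_by_age (exact expectation over the
# discrete sex x stage x year covariate distribution; no randomness)
calibrate_availability <- function(cfg) {
  marg <- cohort_marginals()
  beta <- cfg$availability_model
  groups <- c("lt55", "a5569", "ge70")
  target <- cfg$n_by_age / (cfg$n_total * cfg$age_mix[groups])
  vapply(groups, function(g) {
    p_male <- marg$sex_male[[g]]
    p_sthigh <- sum(marg$stage[g, 3:4])
    cells <- expand.grid(male = c(0, 1), sthigh = c(0, 1),
                         year = marg$years)
    wts <- ifelse(cells$male == 1, p_male, 1 - p_male) *
      ifelse(cells$sthigh == 1, p_sthigh, 1 - p_sthigh) /
      length(marg$years)
    lin <- beta[["sex_male"]] * cells$male +
      beta[["stage_high"]] * cells$sthigh +
      beta[["year"]] * (cells$year - 2000)
    f <- function(a) sum(wts * stats::plogis(a + lin)) - target[[g]]
    stats::uniroot(f, c(-15, 15))$root
  }, numeric(1))
}

# half-lognormal draws strictly above (high) or below (low) a cutpoint
split_lognormal <- function(state_high, cut, sdlog) {
  z <- abs(stats::rnorm(length(state_high))) * sdlog
  cut * exp(ifelse(state_high, z, -z))
}

# zero-inflated lognormal, independent of outcome states
zi_lognormal <- function(n, p_zero, med, sdlog) {
  v <- stats::rlnorm(n, log(med), sdlog)
  v[stats::runif(n) < p_zero] <- 0
  v
}

#' Generate a synthetic incident-cancer cohort table
#'
#' Draws `n_total` cases with age (uniform within the bands 45-54, 55-69,
#' 70-85), age-structured covariates, a tissue-availability flag from the
#' calibrated logistic availability model, and — for available cases —
#' per-case vessel densities whose binary high/low states follow the planted
#' `p_high_by_age` and whose continuous values fall strictly on the matching
#' side of the documented cutpoints. Molecular covariates are `NA` for
#' unavailable cases (no tissue, no assay); missingness among available
#' cases is injected at `missing_rates`.
#'
#' @param config A [cohort_sim_config()].
#' @return Tibble with one row per case.
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_total
  marg <- cohort_marginals()
  grp_keys <- c("lt55", "a5569", "ge70")
  gi <- sample.int(3L, n, replace = TRUE,
                   prob = config$age_mix[grp_keys])
  g <- grp_keys[gi]
  age <- numeric(n)
  age[g == "lt55"] <- stats::runif(sum(g == "lt55"), 45, 55)
  age[g == "a5569"] <- stats::runif(sum(g == "a5569"), 55, 70)
  age[g == "ge70"] <- stats::runif(sum(g == "ge70"), 70, 86)
  age <- floor(age)
  age_group <- factor(AGE_GROUPS[4L - gi], levels = AGE_GROUPS)

  draw_cat <- function(mat, labels) {
    out <- character(n)
    for (k in grp_keys) {
      sel <- g == k
      out[sel] <- sample(labels, sum(sel), replace = TRUE, prob = mat[k, ])
    }
    out
  }
  sex <- ifelse(stats::runif(n) < marg$sex_male[g], "male", "female")
  stage <- draw_cat(marg$stage, c("I", "II", "III", "IV"))
  location <- draw_cat(marg$location,
                       c("proximal colon", "distal colon", "rectum"))
  line1_cat <- draw_cat(marg$line1, c("<=55", "55-65", ">65"))
  msi <- ifelse(stats::runif(n) < marg$msi_high[g], "MSI-high", "non-MSI-high")
  cimp <- ifelse(stats::runif(n) < marg$cimp_high[g], "high", "negative/low")
  kras <- ifelse(stats::runif(n) < marg$kras_mut, "mutated", "wild-type")
  braf <- ifelse(stats::runif(n) < marg$braf_mut, "mutated", "wild-type")
  pik3ca <- ifelse(stats::runif(n) < marg$pik3ca_mut, "mutated", "wild-type")
  famhx <- ifelse(stats::runif(n) < marg$famhx_present, "present", "absent")
  bmi <- round(stats::rlnorm(n, log(26), 0.14), 1)
  pack_years <- ifelse(stats::runif(n) < 0.35, 0,
                       round(stats::rlnorm(n, log(15), 1.0), 1))
  year_dx <- sample(marg$years, n, replace = TRUE)

  lin <- config$age_intercepts[g] +
    config$availability_model[["sex_male"]] * (sex == "male") +
    config$availability_model[["stage_high"]] * (stage %in% c("III", "IV")) +
    config$availability_model[["year"]] * (year_dx - 2000)
  available <- stats::runif(n) < stats::plogis(lin)

  out <- tibble::tibble(
    case_id = sprintf("case%05d", seq_len(n)),
    age = age, age_group = age_group, sex = sex, bmi = bmi,
    pack_years = pack_years, famhx = famhx, location = location,
    stage = stage, msi = msi, cimp = cimp, line1 = line1_cat,
    kras = kras, braf = braf, pik3ca = pik3ca, year_dx = year_dx,
    tissue_available = available)

  # outcome states and densities for available cases
  na_col <- rep(NA_real_, n)
  dens <- list(density_overall = na_col, density_micro = na_col,
               density_collapsed = na_col, density_patent = na_col,
               density_ACKR1 = na_col, density_CD36 = na_col,
               density_KDR = na_col, density_LAMB1 = na_col,
               density_MADCAM1 = na_col)
  av <- which(available)
  n_av <- length(av)
  p_of <- function(outcome) {
    unname(config$p_high_by_age[[outcome]][g[av]])
  }
  st_overall <- stats::runif(n_av) < p_of("overall")
  st_micro <- stats::runif(n_av) < p_of("micro")
  st_lamb1 <- stats::runif(n_av) < p_of("lamb1")
  cuts <- config$cutpoints
  dens$density_overall[av] <- split_lognormal(st_overall, cuts[["overall"]], 0.50)
  dens$density_micro[av] <- split_lognormal(st_micro, cuts[["micro"]], 0.65)
  lamb1 <- split_lognormal(st_lamb1, cuts[["lamb1"]], 0.80)
  lamb1[!st_lamb1 & stats::runif(n_av) < 0.70] <- 0
  dens$density_LAMB1[av] <- lamb1
  dens$density_collapsed[av] <- stats::rlnorm(n_av, log(34), 0.45)
  dens$density_patent[av] <- stats::rlnorm(n_av, log(27), 0.50)
  dens$density_ACKR1[av] <- zi_lognormal(n_av, 0.55, 4, 0.8)
  dens$density_CD36[av] <- zi_lognormal(n_av, 0.45, 5, 0.9)
  dens$density_KDR[av] <- zi_lognormal(n_av, 0.35, 12, 0.9)
  dens$density_MADCAM1[av] <- zi_lognormal(n_av, 0.70, 2.5, 0.8)
  for (nm in names(dens)) out[[nm]] <- dens[[nm]]
  out$n_cores <- NA_integer_
  out$n_cores[av] <- sample(1:3, n_av, replace = TRUE,
                            prob = c(0.45, 0.40, 0.15))

  # missingness (available cases; molecular covariates are NA when
  # unavailable by construction)
  mr <- config$missing_rates
  mol <- c(msi = "msi", cimp = "cimp", kras = "kras", braf = "braf",
           pik3ca = "pik3ca", line1 = "line1")
  for (nm in names(mol)) {
    col <- mol[[nm]]
    out[[col]][!available] <- NA_character_
    hit <- av[stats::runif(n_av) < mr[[nm]]]
    out[[col]][hit] <- NA_character_
  }
  for (nm in c("famhx", "location")) {
    out[[nm]][stats::runif(n) < mr[[nm]]] <- NA_character_
  }
  out
}
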