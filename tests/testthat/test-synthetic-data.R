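test_that("simulator configs validate their invariants", {
  expect_error(image_sim_config(class_mixture = c(micro = 0.5, collapsed = 0.3,
                                                  patent = 0.1, irregular = 0.2)),
               "sum to 1")
  expect_error(image_sim_config(marker_rates = c(ACKR1 = 1.2, CD36 = 0.1,
                                                 KDR = 0.1, LAMB1 = 0.1,
                                                 MADCAM1 = 0.1)),
               "\\[0, 1\\]")
  expect_error(image_sim_config(image_size = 0))
  expect_error(generate_vessel_shape("tube"), "unknown vessel class")
  expect_error(cohort_sim_config(p_high_by_age = list(overall = c(2, 0, 0))))
})

test_that("vessel archetypes satisfy their geometric construction rules", {
  set.seed(12)
  for (i in 1:40) {
    fm <- compute_features(generate_vessel_shape("micro"))
    expect_gt(fm$Solidity, 0.9)
    expect_lt(fm$Eccentricity, 0.7)
    fc <- compute_features(generate_vessel_shape("collapsed"))
    expect_gt(fc$Eccentricity, 0.95)
  }
})

test_that("archetype classes are geometrically separable (1-NN centroid)", {
  feats <- labeled_shape_features(1000, seed = 31)
  z <- standardize_features(feats, class_col = "class")$features
  X <- as.matrix(z[, MORPH_FEATURES])
  cls <- z$class
  centroids <- apply(X, 2, function(col) tapply(col, cls, mean))
  d2 <- sapply(rownames(centroids), function(cl) {
    rowSums(sweep(X, 2, centroids[cl, ])^2)
  })
  assigned <- colnames(d2)[max.col(-d2)]
  for (cl in VESSEL_CLASSES) {
    expect_lt(mean(assigned[cls == cl] != cl), 0.10)
  }
})

test_that("zero-density and zero-marker configs degenerate correctly", {
  cfg <- small_image_config(seed = 3, target_density = 0)
  g <- generate_core_image(cfg)
  expect_equal(nrow(g$truth$vessels), 0)
  expect_true(all(g$stack$channels$CD34 == cfg$background_level))
  cfg2 <- small_image_config(seed = 3, marker_rates = c(
    ACKR1 = 0, CD36 = 0, KDR = 0, LAMB1 = 0, MADCAM1 = 0))
  g2 <- generate_core_image(cfg2)
  for (mk in AUX_MARKERS) {
    expect_false(any(g2$truth$vessels[[paste0(mk, "_pos")]]))
    expect_true(all(g2$stack$channels[[mk]] == cfg2$background_level))
  }
})

test_that("an over-dense configuration fails with an explicit message", {
  cfg <- image_sim_config(image_size = 280L, target_density = 30000,
                          epithelial_fraction = 0, seed = 1)
  expect_error(generate_core_image(cfg), "too high")
})

test_that("planted vessel count follows the Poisson law and masks stay in tissue", {
  g <- small_core()   # 512 px -> 0.0655 mm^2 tissue
  lambda <- 197 * g$truth$tissue_mm2
  expect_lt(abs(nrow(g$truth$vessels) - lambda), 3 * sqrt(lambda) + 1)
  for (px in g$truth$vessels$pixels) {
    expect_true(all(px >= 1 & px <= 512))
  }
  expect_true(all(g$truth$vessels$class %in% VESSEL_CLASSES))
  # planted marker patches strictly exceed 5% of vessel area when positive
  ch <- g$stack$channels
  cfg <- g$truth$config
  for (i in seq_len(nrow(g$truth$vessels))) {
    px <- g$truth$vessels$pixels[[i]]
    for (mk in AUX_MARKERS) {
      frac <- mean(ch[[mk]][px] > cfg$background_level)
      if (g$truth$vessels[[paste0(mk, "_pos")]][i]) {
        expect_gt(frac, 0.05)
      } else {
        expect_lte(frac, 0.05)
      }
    }
  }
})

test_that("ground-truth class mixture converges to the planted mixture", {
  set.seed(610)
  n <- 6000
  cls <- table(factor(sample(VESSEL_CLASSES, n, replace = TRUE,
                             prob = image_sim_config()$class_mixture),
                      levels = VESSEL_CLASSES))
  # chi-square GoF on the sampler the generator uses for class draws
  gof <- chisq.test(cls, p = image_sim_config()$class_mixture)
  expect_gt(gof$p.value, 0.01)
  # and on actual generated cores (pooled)
  cores <- simulate_cores(3, small_image_config(), seed = 15)
  pooled <- table(factor(unlist(lapply(cores,
                                       function(g) g$truth$vessels$class)),
                         levels = VESSEL_CLASSES))
  gof2 <- chisq.test(pooled, p = image_sim_config()$class_mixture)
  expect_gt(gof2$p.value, 0.01)
})

test_that("core TIFF and ground-truth serialization round-trip", {
  g <- small_core()
  path <- withr::local_tempfile(fileext = ".tif")
  write_core_tiff(g$stack, path)
  back <- read_core_tiff(path)
  expect_equal(back$channels, g$stack$channels)
  expect_equal(back$pixel_size, 0.5)
  expect_equal(back$core_id, g$stack$core_id)
  base <- withr::local_tempfile()
  write_ground_truth(g$truth, base)
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(nrow(js$vessels), nrow(g$truth$vessels))
  lab <- round(tiff::readTIFF(paste0(base, "_labels.tif")) * 65535)
  expect_equal(max(lab), nrow(g$truth$vessels))
})

test_that("cohort generator hits the expected availability structure", {
  cfg <- cohort_sim_config(seed = 2024)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 4476)
  n_av <- sum(coh$tissue_available)
  expect_lt(abs(n_av - 843), 3 * sqrt(843))
  # age groups partition the age range and match continuous age
  expect_true(all(coh$age_group[coh$age < 55] == "<55"))
  expect_true(all(coh$age_group[coh$age >= 70] == ">=70"))
  # availability-1 config: everyone available
  cfg1 <- cohort_sim_config(seed = 9)
  cfg1$age_intercepts[] <- 50
  expect_true(all(generate_cohort(cfg1)$tissue_available))
  # densities only for available cases, strictly split at the cutpoints
  av <- coh[coh$tissue_available, ]
  expect_true(all(is.na(coh$density_overall[!coh$tissue_available])))
  expect_true(all(av$density_overall != 197))
  expect_true(all(av$density_LAMB1 != 8))
})

test_that("cohort missingness appears at the configured rates", {
  coh <- generate_cohort(cohort_sim_config(seed = 5150))
  av <- coh[coh$tissue_available, ]
  mr <- cohort_sim_config()$missing_rates
  for (v in c("cimp", "pik3ca")) {
    rate <- mean(is.na(av[[v]]))
    expect_lt(abs(rate - mr[[v]]),
              3 * sqrt(mr[[v]] * (1 - mr[[v]]) / nrow(av)) + 0.001)
  }
  expect_true(all(is.na(coh$msi[!coh$tissue_available])))
})

test_that("null planted association yields odds ratios near 1", {
  cfg <- cohort_sim_config(
    n_total = 20000L,
    p_high_by_age = list(overall = c(lt55 = 0.5, a5569 = 0.5, ge70 = 0.5),
                         micro = c(lt55 = 0.5, a5569 = 0.5, ge70 = 0.5),
                         lamb1 = c(lt55 = 0.5, a5569 = 0.5, ge70 = 0.5)),
    seed = 808)
  cfg$age_intercepts[] <- 50           # keep everyone -> large n
  coh <- generate_cohort(cfg)
  hi <- coh$density_overall > 197
  tab <- table(coh$age_group, hi)
  or_lt55 <- (tab["<55", "TRUE"] / tab["<55", "FALSE"]) /
    (tab[">=70", "TRUE"] / tab[">=70", "FALSE"])
  expect_equal(or_lt55, 1, tolerance = 0.15)
})

test_that("cohort generation is reproducible from its seed", {
  a <- generate_cohort(cohort_sim_config(seed = 123))
  b <- generate_cohort(cohort_sim_config(seed = 123))
  expect_identical(a, b)
  g1 <- generate_core_image(small_image_config(seed = 55))
  g2 <- generate_core_image(small_image_config(seed = 55))
  expect_identical(g1$stack$channels, g2$stack$channels)
  expect_identical(g1$truth$vessels$class, g2$truth$vessels$class)
})
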