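test_that("core areas follow the pixel-count arithmetic", {
  full <- matrix(TRUE, 1600, 1600)
  none <- matrix(FALSE, 1600, 1600)
  a <- compute_core_areas(full, none)
  expect_equal(a$core_mm2, 0.64)
  expect_equal(a$stromal_mm2, 0.64)
  expect_equal(a$epithelial_mm2, 0)
  # KRT over 25% of tissue -> stromal = 0.75 x core
  krt <- none; krt[1:800, 1:800] <- TRUE
  a2 <- compute_core_areas(full, krt)
  expect_equal(a2$stromal_mm2, 0.75 * a2$core_mm2)
  # identity epithelial + stromal = core on random masks
  set.seed(8)
  for (i in 1:5) {
    tis <- matrix(runif(400) > 0.3, 20, 20)
    k <- matrix(runif(400) > 0.6, 20, 20)
    a3 <- compute_core_areas(tis, k)
    expect_equal(a3$epithelial_mm2 + a3$stromal_mm2, a3$core_mm2)
  }
  expect_true(compute_core_areas(none, none)$flagged)
})

test_that("vessel extraction respects connectivity and minimum size", {
  m <- matrix(FALSE, 30, 30)
  m[3:7, 3:7] <- TRUE
  m[20:24, 20:24] <- TRUE
  cfg <- phenotyping_config(min_vessel_area_px = 1)
  expect_equal(nrow(extract_vessels(m, cfg)), 2)
  # squares touching only at a corner
  d <- matrix(FALSE, 20, 20)
  d[3:6, 3:6] <- TRUE
  d[7:10, 7:10] <- TRUE
  cfg8 <- phenotyping_config(connectivity = 8, min_vessel_area_px = 1)
  cfg4 <- phenotyping_config(connectivity = 4, min_vessel_area_px = 1)
  expect_equal(nrow(extract_vessels(d, cfg8)), 1)
  expect_equal(nrow(extract_vessels(d, cfg4)), 2)
  # small components are discarded
  s <- matrix(FALSE, 20, 20)
  s[2:3, 2:3] <- TRUE          # 4 px
  s[10:14, 10:14] <- TRUE      # 25 px
  expect_equal(extract_vessels(s, phenotyping_config())$area_px, 25L)
  expect_equal(nrow(extract_vessels(matrix(FALSE, 5, 5))), 0)
  # deterministic row-major ids
  v <- extract_vessels(m, cfg)
  expect_equal(v$vessel_id, 1:2)
  expect_lt(v$centroid_y_um[1], v$centroid_y_um[2])
})

test_that("marker flags obey the strict 5% rule", {
  m <- matrix(FALSE, 30, 30)
  m[6:15, 6:15] <- TRUE   # 100-px vessel
  v <- extract_vessels(m, phenotyping_config())
  mk6 <- matrix(FALSE, 30, 30); mk6[6, 6:11] <- TRUE   # 6 px overlap
  mk5 <- matrix(FALSE, 30, 30); mk5[6, 6:10] <- TRUE   # exactly 5 px
  flags <- assign_marker_flags(v, list(KDR = mk6, ACKR1 = mk5))
  expect_true(flags$KDR_pos)
  expect_false(flags$ACKR1_pos)    # 0.05 is not > 0.05
  # monotone: enlarging a marker mask never flips positive -> negative
  mk_big <- mk5; mk_big[7, 6:10] <- TRUE
  flags2 <- assign_marker_flags(v, list(ACKR1 = mk_big))
  expect_true(flags2$ACKR1_pos >= flags$ACKR1_pos)
})

test_that("densities follow counts over core area and partition by class", {
  areas <- tibble::tibble(core_mm2 = 0.64, epithelial_mm2 = 0.24,
                          stromal_mm2 = 0.4, flagged = FALSE)
  v <- tibble::tibble(vessel_id = 1:64,
                      morph_class = rep(VESSEL_CLASSES, 16))
  for (mk in AUX_MARKERS) v[[paste0(mk, "_pos")]] <- FALSE
  d <- vessel_densities(v, areas)
  expect_equal(d$density_overall, 100)
  expect_equal(d$density_micro + d$density_collapsed + d$density_patent +
                 d$density_irregular, d$density_overall)
  d0 <- vessel_densities(v[0, ], areas)
  expect_equal(d0$density_overall, 0)
  dna <- vessel_densities(v, dplyr::mutate(areas, core_mm2 = 0))
  expect_true(is.na(dna$density_overall))
})

test_that("core records bridge phenotyping to per-case aggregation", {
  ph <- small_phenotyped()
  ph$vessels$morph_class <- sample(VESSEL_CLASSES, nrow(ph$vessels),
                                   replace = TRUE)
  rec <- core_record(ph, case_id = "case001")
  expect_equal(rec$count_overall, nrow(ph$vessels))
  expect_true(rec$qc_pass)
  agg <- aggregate_case_metrics(rec)
  expect_equal(agg$density_overall,
               rec$count_overall / rec$core_area_mm2)
  expect_equal(agg$n_cores, 1L)
})

test_that("binary masks round-trip through TIFF with provenance", {
  m <- small_phenotyped()$masks$masks$CD34
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask_tiff(m, path)
  back <- read_mask_tiff(path)
  expect_identical(unclass(back)[, ], unclass(m)[, ])
  expect_equal(attr(back, "channel"), "CD34")
})

test_that("noiseless simulated cores are recovered exactly", {
  g <- small_core()
  ph <- small_phenotyped()
  # component count equals the planted count
  expect_equal(nrow(ph$vessels), nrow(g$truth$vessels))
  m <- match_ground_truth(ph$vessels, g$truth)
  expect_true(all(!is.na(m$true_id)))
  expect_equal(sort(m$true_id), seq_len(nrow(g$truth$vessels)))
  # marker flags equal the planted flags vessel by vessel
  for (mk in AUX_MARKERS) {
    expect_identical(m[[paste0(mk, "_pos")]],
                     g$truth$vessels[[paste0(mk, "_pos")]][m$true_id])
  }
  # recovered epithelial fraction tracks the planted fraction
  expect_equal(ph$areas$epithelial_mm2 / ph$areas$core_mm2,
               mean(g$truth$epithelium), tolerance = 0.05)
  expect_equal(ph$areas$core_mm2, g$truth$tissue_mm2, tolerance = 0.02)
})

test_that("whole-scene translation leaves densities unchanged", {
  g <- small_core()
  ph <- small_phenotyped()
  shift <- 40L
  shifted <- g$stack
  shifted$channels <- lapply(g$stack$channels, function(ch) {
    out <- matrix(ch[1, 1], nrow(ch), ncol(ch))
    out[(shift + 1):nrow(ch), (shift + 1):ncol(ch)] <-
      ch[1:(nrow(ch) - shift), 1:(ncol(ch) - shift)]
    out
  })
  ph2 <- suppressWarnings(phenotype_core(shifted))
  d1 <- vessel_densities(ph$vessels, ph$areas)
  d2 <- vessel_densities(ph2$vessels, ph2$areas)
  # vessels fully inside both frames: counts should match within the few
  # vessels clipped at the trailing border
  expect_lt(abs(d2$density_overall - d1$density_overall) /
              d1$density_overall, 0.1)
})
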