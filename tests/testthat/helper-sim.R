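# Small simulated fixtures shared across test files. Built once per test run.

small_image_config <- function(seed = NULL, ...) {
  image_sim_config(image_size = 512L, seed = seed, ...)
}

# a cached small core + its phenotyping output (several tests reuse it)
the <- new.env(parent = emptyenv())

small_core <- function() {
  if (is.null(the$core)) {
    the$core <- generate_core_image(small_image_config(seed = 4281))
  }
  the$core
}

small_phenotyped <- function() {
  if (is.null(the$phen)) {
    the$phen <- suppressWarnings(phenotype_core(small_core()$stack))
  }
  the$phen
}

# labeled vessel features drawn straight from the shape generator
labeled_shape_features <- function(n_per_class, seed = 1L) {
  set.seed(seed)
  purrr::map_dfr(VESSEL_CLASSES, function(cl) {
    feats <- purrr::map_dfr(seq_len(n_per_class), function(i) {
      compute_features(generate_vessel_shape(cl))
    })
    dplyr::mutate(feats, class = cl)
  })
}
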