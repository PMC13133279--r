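Package: vesselphen
Title: Tumor Vessel Phenotyping from Multiplexed Immunofluorescence Tissue Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, ground-truthed pipeline for quantifying tumor blood
    vessels in multiplexed immunofluorescence tissue-microarray core images and
    relating per-case vessel densities to age at diagnosis. Includes a
    synthetic-data module that simulates spectrally unmixed 8-channel core
    images with planted vessel morphologies and endothelial-marker phenotypes,
    and an epidemiological cohort simulator with planted age-density
    associations; standardized channel preprocessing (9x9 mean filter, Otsu
    binarization, disk closing/opening); CD34+ vessel extraction with the
    strict more-than-5-percent marker-area positivity rule; ten regionprops-style
    morphometric features and a 1000-tree random-forest morphology classifier
    (micro, collapsed, patent, irregular); and inverse-probability-weighted
    multivariable logistic regression with backward elimination, Spearman
    age-trend tests, and multiplicity control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
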