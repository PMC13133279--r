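#' Random-forest classifier configuration
#'
#' The forest mirrors the labeling protocol of the morphology classifier:
#' 1000 trees, four candidate features per node split, 100 vessels per class
#' in both the training and the validation set.
#'
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate features per split (default 4).
#' @param train_per_class,val_per_class Stratified sample sizes (default 100
#'   each).
#' @param seed RNG seed for splitting and training (default 1).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 1000L, mtry = 4L,
                              train_per_class = 100L, val_per_class = 100L,
                              seed = 1L) {
  stopifnot(n_trees >= 1, mtry >= 1, mtry <= length(MORPH_FEATURES),
            train_per_class >= 1, val_per_class >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 train_per_class = as.integer(train_per_class),
                 val_per_class = as.integer(val_per_class),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified train/validation split of labeled vessels
#'
#' Draws `train_per_class` vessels per class for training and, from the
#' remaining vessels, `val_per_class` per class for validation; the two sets
#' are disjoint and the draw is seeded.
#'
#' @param labeled Tibble with a `class` column over [VESSEL_CLASSES] and the
#'   [MORPH_FEATURES] columns.
#' @param config A [classifier_config()].
#' @return List with `train` and `validation` tibbles.
#' @export
split_train_validation <- function(labeled, config = classifier_config()) {
  stopifnot(is.data.frame(labeled), "class" %in% names(labeled))
  need <- config$train_per_class + config$val_per_class
  counts <- table(factor(labeled$class, levels = VESSEL_CLASSES))
  short <- names(counts)[counts < need]
  if (length(short) > 0L) {
    stop("insufficient labeled vessels (need ", need, " per class) for: ",
         paste0(short, " (", counts[short], ")", collapse = ", "))
  }
  set.seed(config$seed)
  labeled <- dplyr::mutate(labeled, .row = dplyr::row_number())
  train_rows <- labeled |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_sample(n = config$train_per_class) |>
    dplyr::pull(.data$.row)
  val_rows <- labeled |>
    dplyr::filter(!.data$.row %in% train_rows) |>
    dplyr::group_by(.data$class) |>
    dplyr::slice_sample(n = config$val_per_class) |>
    dplyr::pull(.data$.row)
  list(train = dplyr::select(labeled[train_rows, ], -".row"),
       validation = dplyr::select(labeled[val_rows, ], -".row"))
}

#' Train the vessel-morphology random forest
#'
#' Bootstrap-sampled trees grown to purity on the raw (unstandardized)
#' morphological features — forests are scale-invariant, so no z-scoring is
#' applied before training.
#'
#' @param train Tibble with `class` and the [MORPH_FEATURES] columns.
#' @param config A [classifier_config()].
#' @return Object of class `vessel_rf` wrapping the fitted
#'   [randomForest::randomForest] model.
#' @export
train_vessel_rf <- function(train, config = classifier_config()) {
  stopifnot(is.data.frame(train), all(MORPH_FEATURES %in% names(train)))
  y <- factor(train$class, levels = VESSEL_CLASSES)
  if (length(unique(train$class)) < 2L) {
    stop("degenerate training set: at least two classes are required")
  }
  x <- as.data.frame(train[, MORPH_FEATURES])
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = config$mtry,
    importance = TRUE)
  structure(list(forest = fit, config = config,
                 classes = VESSEL_CLASSES),
            class = "vessel_rf")
}

#' @export
print.vessel_rf <- function(x, ...) {
  cat("<vessel_rf> ", x$config$n_trees, " trees, mtry ", x$config$mtry,
      ", classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify vessels with a trained forest
#'
#' Majority vote over the trees; exact vote ties are broken toward the
#' earliest class in the fixed documented order (micro, collapsed, patent,
#' irregular), making prediction deterministic for a fixed model. Rows with
#' missing features are not classified; their indices are reported in the
#' `failures` attribute.
#'
#' @param model A `vessel_rf`.
#' @param vessels Tibble with the [MORPH_FEATURES] columns.
#' @return `vessels` with a `morph_class` column (`NA` for failed rows);
#'   `attr(, "failures")` lists row indices with incomplete features.
#' @export
classify_vessels <- function(model, vessels) {
  stopifnot(inherits(model, "vessel_rf"), is.data.frame(vessels))
  if (nrow(vessels) == 0L) {
    vessels$morph_class <- character()
    return(vessels)
  }
  x <- as.data.frame(vessels[, MORPH_FEATURES])
  ok <- stats::complete.cases(x)
  cls <- rep(NA_character_, nrow(vessels))
  if (any(ok)) {
    votes <- stats::predict(model$forest, x[ok, , drop = FALSE],
                            type = "vote", norm.votes = FALSE)
    votes <- votes[, VESSEL_CLASSES, drop = FALSE]
    cls[ok] <- VESSEL_CLASSES[apply(votes, 1L, which.max)]
  }
  vessels$morph_class <- cls
  structure(vessels, failures = which(!ok))
}

#' Evaluate a trained classifier on a labeled set
#'
#' @param model A `vessel_rf`.
#' @param labeled Tibble with `class` and the [MORPH_FEATURES] columns.
#' @return Object of class `rf_eval`: `accuracy`, 4x4 `confusion` matrix
#'   (rows = true), per-class `recall`, normalized mean-decrease-in-Gini
#'   `importance` tibble, and `n`.
#' @export
evaluate_classifier <- function(model, labeled) {
  stopifnot(nrow(labeled) > 0L, "class" %in% names(labeled))
  pred <- classify_vessels(model, labeled)$morph_class
  truth <- factor(labeled$class, levels = VESSEL_CLASSES)
  pred <- factor(pred, levels = VESSEL_CLASSES)
  confusion <- table(true = truth, predicted = pred)
  acc <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / rowSums(confusion)
  imp <- randomForest::importance(model$forest, type = 2L)[, 1L]
  imp_tbl <- tibble::tibble(feature = names(imp),
                            importance = unname(imp) / sum(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
  structure(list(accuracy = acc, confusion = unclass(confusion),
                 recall = recall, importance = imp_tbl,
                 n = nrow(labeled)),
            class = "rf_eval")
}

#' @export
print.rf_eval <- function(x, ...) {
  cat("<rf_eval> n =", x$n, " accuracy =", round(x$accuracy, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' Interobserver agreement between two raters
#'
#' Concordance rate (fraction of identical labels) and unweighted Cohen's
#' kappa, with expected agreement from the product of rater marginals.
#' Degenerate marginals with expected agreement 1 yield kappa 0 with a
#' warning.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Tibble with `concordance`, `kappa`, `n`.
#' @export
interobserver_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  n <- length(labels_a)
  stopifnot(n > 0L)
  lev <- union(unique(labels_a), unique(labels_b))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - p_e) < 1e-12) {
    warning("degenerate rater marginals: expected agreement is 1; kappa set to 0")
    kappa <- 0
  } else {
    kappa <- (p_o - p_e) / (1 - p_e)
  }
  tibble::tibble(concordance = p_o, kappa = kappa, n = n)
}

#' Simulate a second rater by relabeling with noise
#'
#' Utility for agreement studies on synthetic labels: each label is replaced
#' with a uniformly drawn different class with probability `noise_rate`.
#'
#' @param labels Character vector over [VESSEL_CLASSES].
#' @param noise_rate Per-label disagreement probability.
#' @return Character vector of the same length.
#' @export
relabel_with_noise <- function(labels, noise_rate = 0.09) {
  stopifnot(noise_rate >= 0, noise_rate <= 1)
  flip <- stats::runif(length(labels)) < noise_rate
  labels[flip] <- vapply(labels[flip], function(cl) {
    sample(setdiff(VESSEL_CLASSES, cl), 1L)
  }, character(1))
  labels
}
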