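#' Names of the ten morphological features
#' @export
MORPH_FEATURES <- c("Area", "Perimeter", "Circularity", "ConvexArea",
                    "Eccentricity", "EquivDiameter", "Extent",
                    "MajorAxisLength", "MinorAxisLength", "Solidity")

# calibration factor for the sqrt(2)-weighted Moore contour length;
# makes the perimeter estimator unbiased over line orientations
# (Vossepoel-Smeulders weights 0.9481 / 0.9481*sqrt(2))
PERIMETER_CALIBRATION <- 0.9481

#' Morphological features of one vessel mask
#'
#' Computes the ten shape descriptors used by the morphology classifier:
#' * `Area`: foreground pixel count (holes excluded).
#' * `Perimeter`: length of the traced outer contour; diagonal steps weighted
#'   `sqrt(2)`, with a global orientation-calibration factor 0.9481 so digital
#'   disks measure their true circumference.
#' * `Circularity`: `4 * pi * Area / Perimeter^2` (plain form, no small-object
#'   correction; `NA` for degenerate masks with zero perimeter).
#' * `ConvexArea`: pixel count of the rasterized convex hull — the number of
#'   pixel centres lying inside or on the convex hull of the pixel centres —
#'   so `Area <= ConvexArea` holds exactly and digitally convex shapes have
#'   Solidity 1.
#' * `Eccentricity`, `MajorAxisLength`, `MinorAxisLength`: from the ellipse
#'   with the same normalized second central moments (with the 1/12
#'   pixel-square correction).
#' * `EquivDiameter`: `sqrt(4 * Area / pi)`.
#' * `Extent`: `Area` over axis-aligned bounding-box area.
#' * `Solidity`: `Area / ConvexArea`.
#'
#' @param mask Logical matrix containing a single non-empty connected
#'   component (holes allowed; they are excluded from `Area`).
#' @return One-row tibble with the [MORPH_FEATURES] columns.
#' @export
compute_features <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: no features to compute")
  features_from_coords(idx[, 1L], idx[, 2L])
}

# core feature computation on 0-based-agnostic pixel coordinates
features_from_coords <- function(r, c) {
  n <- length(r)
  area <- n
  # bounding box
  bbox <- (max(r) - min(r) + 1) * (max(c) - min(c) + 1)
  extent <- area / bbox
  # normalized second central moments (pixel modelled as a unit square)
  rc <- r - mean(r)
  cc <- c - mean(c)
  uxx <- mean(cc^2) + 1 / 12
  uyy <- mean(rc^2) + 1 / 12
  uxy <- mean(rc * cc)
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(max(uxx + uyy - common, 0))
  ecc <- sqrt(max(1 - (minor / major)^2, 0))
  # local mask with a 1-px pad for tracing / hull
  lr <- r - min(r) + 2L
  lc <- c - min(c) + 2L
  m <- matrix(FALSE, max(lr) + 1L, max(lc) + 1L)
  m[cbind(lr, lc)] <- TRUE
  perim <- trace_perimeter(m) * PERIMETER_CALIBRATION
  circ <- if (perim > 0) 4 * pi * area / perim^2 else NA_real_
  hull_area <- convex_area(m)
  tibble::tibble(
    Area = area,
    Perimeter = perim,
    Circularity = circ,
    ConvexArea = hull_area,
    Eccentricity = ecc,
    EquivDiameter = sqrt(4 * area / pi),
    Extent = extent,
    MajorAxisLength = major,
    MinorAxisLength = minor,
    Solidity = area / hull_area
  )
}

# Moore-neighbour tracing of the outer contour; returns the raw
# sqrt(2)-weighted contour length (0 for a single pixel)
trace_perimeter <- function(m) {
  idx <- which(m)
  nr <- nrow(m)
  start <- idx[1L]                     # column-major first: leftmost column,
  sr <- (start - 1L) %% nr + 1L        # topmost row within it -> its W and N
  sc <- (start - 1L) %/% nr + 1L       # neighbours are background
  # clockwise Moore neighbourhood (rows grow downward): W NW N NE E SE S SW
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, -1L, 0L, 0L + 1L, 1L, 1L, 0L, -1L)
  dc[4L] <- 1L
  step_len <- sqrt(dr^2 + dc^2)
  cur_r <- sr; cur_c <- sc
  b <- 1L                              # backtrack direction index (W)
  total <- 0
  first_edge <- NULL
  max_iter <- 4L * length(idx) + 16L
  for (it in seq_len(max_iter)) {
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- (b + k - 1L) %% 8L + 1L     # scan clockwise after the backtrack
      nr2 <- cur_r + dr[d]
      nc2 <- cur_c + dc[d]
      if (m[nr2, nc2]) {
        prev <- (d - 2L) %% 8L + 1L    # last background scanned
        edge <- c(cur_r, cur_c, nr2, nc2)
        if (is.null(first_edge)) {
          first_edge <- edge
        } else if (all(edge == first_edge)) {
          return(total)
        }
        total <- total + step_len[d]
        # new backtrack: direction from the new pixel to `prev` neighbour
        pb_r <- cur_r + dr[prev]
        pb_c <- cur_c + dc[prev]
        b <- which(dr == pb_r - nr2 & dc == pb_c - nc2)
        cur_r <- nr2; cur_c <- nc2
        found <- TRUE
        break
      }
    }
    if (!found) return(0)              # isolated pixel
  }
  total
}

# rasterized convex-hull area: number of pixels whose centers lie inside
# (or on) the convex hull of the pixel centers. Counting centers against
# the center hull makes Area <= ConvexArea exact and gives Solidity 1 for
# every digitally convex shape.
convex_area <- function(m) {
  inner <- m[-c(1L, nrow(m)), -c(1L, ncol(m)), drop = FALSE]
  up    <- m[-c(nrow(m) - 1L, nrow(m)), -c(1L, ncol(m)), drop = FALSE]
  down  <- m[-c(1L, 2L), -c(1L, ncol(m)), drop = FALSE]
  left  <- m[-c(1L, nrow(m)), -c(ncol(m) - 1L, ncol(m)), drop = FALSE]
  right <- m[-c(1L, nrow(m)), -c(1L, 2L), drop = FALSE]
  boundary <- inner & !(up & down & left & right)
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) == 0L) idx <- which(m, arr.ind = TRUE) - 1L
  r <- idx[, 1L]
  c <- idx[, 2L]
  px <- c
  py <- r
  h <- grDevices::chull(px, py)
  if (length(h) < 3L) return(length(which(m)))   # point or line: hull = mask

  hx <- px[h]; hy <- py[h]
  # ensure counter-clockwise orientation
  if (sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy) < 0) {
    hx <- rev(hx); hy <- rev(hy)
  }
  # count pixel centres of the bounding box inside every hull half-plane
  rng_r <- range(r); rng_c <- range(c)
  cand_r <- rep(rng_r[1]:rng_r[2], times = rng_c[2] - rng_c[1] + 1L)
  cand_c <- rep(rng_c[1]:rng_c[2], each = rng_r[2] - rng_r[1] + 1L)
  inside <- rep(TRUE, length(cand_r))
  nv <- length(hx)
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    inside <- inside &
      (ex * (cand_r - hy[k]) - ey * (cand_c - hx[k])) >= -1e-9
  }
  sum(inside)
}

#' Append morphological feature columns to a vessel table
#'
#' @param vessels Tibble with a `pixels` list-column of 2-column matrices
#'   (row, col), as produced by [extract_vessels()].
#' @return `vessels` with the ten [MORPH_FEATURES] columns appended.
#' @export
add_morph_features <- function(vessels) {
  stopifnot(is.data.frame(vessels), "pixels" %in% names(vessels))
  feats <- purrr::map_dfr(vessels$pixels, function(px) {
    features_from_coords(px[, 1L], px[, 2L])
  })
  dplyr::bind_cols(vessels, feats)
}

#' Z-score a feature table and summarize per-class medians
#'
#' Each feature column is standardized column-wise to mean 0 and SD 1.
#' Constant columns become all zeros with a warning. When `class_col` is
#' given, the per-class medians of the standardized features are returned as
#' well (the summary shown alongside variable-importance plots).
#'
#' @param features Data frame containing the [MORPH_FEATURES] columns.
#' @param class_col Optional name of a class label column.
#' @return List with `features` (standardized tibble, non-feature columns
#'   untouched) and `class_medians` (tibble or `NULL`).
#' @export
standardize_features <- function(features, class_col = NULL) {
  stopifnot(is.data.frame(features))
  cols <- intersect(MORPH_FEATURES, names(features))
  if (nrow(features) < 2L) stop("need at least two rows to standardize")
  out <- features
  for (cl in cols) {
    x <- out[[cl]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("feature '", cl, "' has zero variance; standardized to 0")
      out[[cl]] <- rep(0, length(x))
    } else {
      out[[cl]] <- (x - mean(x)) / s
    }
  }
  medians <- NULL
  if (!is.null(class_col)) {
    medians <- out |>
      dplyr::group_by(.data[[class_col]]) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(cols), stats::median),
                       .groups = "drop")
  }
  list(features = tibble::as_tibble(out), class_medians = medians)
}
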