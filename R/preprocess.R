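#' Smooth a channel with a square averaging filter
#'
#' Applies the standardized noise-reduction step of the image pipeline: every
#' output pixel is the mean of the `size x size` window centred on it.
#' Borders are handled by symmetric reflection, so tissue touching the core
#' edge is not darkened. The implementation uses integral images and is exact
#' (no FFT round-off beyond double precision).
#'
#' @param image Numeric matrix of intensities.
#' @param size Odd window side length in pixels (default 9).
#' @return Numeric matrix with the same dimensions as `image`.
#' @export
smooth_channel <- function(image, size = 9L) {
  stopifnot(is.matrix(image), is.numeric(image))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) {
    stop("`size` must be a positive odd integer")
  }
  if (nrow(image) < size || ncol(image) < size) {
    stop("image smaller than the ", size, "x", size, " averaging window")
  }
  r <- (size - 1L) %/% 2L
  padded <- reflect_pad(image, r)
  # summed-area table with a zero first row/column
  sat <- rbind(0, cbind(0, padded))
  sat <- apply(sat, 2L, cumsum)
  sat <- t(apply(sat, 1L, cumsum))
  n <- nrow(image)
  m <- ncol(image)
  i1 <- seq_len(n)          # top-left corner (in padded frame, minus one)
  j1 <- seq_len(m)
  i2 <- i1 + 2L * r         # bottom-right corner
  j2 <- j1 + 2L * r
  win <- sat[i2 + 1L, j2 + 1L, drop = FALSE] - sat[i1, j2 + 1L, drop = FALSE] -
    sat[i2 + 1L, j1, drop = FALSE] + sat[i1, j1, drop = FALSE]
  win / (size * size)
}

# symmetric (half-sample) reflection padding by r pixels on each side
reflect_pad <- function(image, r) {
  if (r == 0L) return(image)
  n <- nrow(image)
  m <- ncol(image)
  ri <- c(r:1, seq_len(n), n:(n - r + 1L))
  ci <- c(r:1, seq_len(m), m:(m - r + 1L))
  image[ri, ci, drop = FALSE]
}

#' Binarize an intensity image with Otsu's method
#'
#' Chooses the threshold that maximizes the between-class variance of the
#' intensity histogram and returns the mask of pixels *strictly above* the
#' threshold. For integer-valued images the histogram is exact (every observed
#' value is a candidate threshold); continuous images are binned.
#'
#' @param image Numeric matrix with at least two distinct values. A constant
#'   image yields an all-background mask with a warning.
#' @param nbins Number of histogram bins used for non-integer images
#'   (default 65536, i.e. 16-bit resolution).
#' @return A [binary_mask()] object; the chosen threshold is in
#'   `attr(, "threshold")`.
#' @export
binarize_otsu <- function(image, nbins = 65536L) {
  stopifnot(is.matrix(image), is.numeric(image))
  v <- as.vector(image)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(binary_mask(matrix(FALSE, nrow(image), ncol(image)),
                       channel = NA_character_, steps = "otsu",
                       threshold = rng[1]))
  }
  integral <- all(v == floor(v)) && (rng[2] - rng[1]) < 2^24
  if (integral) {
    shift <- rng[1] - 1
    counts <- tabulate(v - shift, nbins = rng[2] - shift)
    levels <- seq(rng[1], rng[2])
  } else {
    width <- (rng[2] - rng[1]) / nbins
    idx <- pmin(floor((v - rng[1]) / width), nbins - 1) + 1
    counts <- tabulate(idx, nbins = nbins)
    # bin upper edges serve as candidate thresholds; last bin top = max
    levels <- rng[1] + seq_len(nbins) * width
  }
  keep <- counts > 0L
  counts <- counts[keep]
  levels <- levels[keep]
  thr <- otsu_threshold(levels, counts)
  binary_mask(matrix(v > thr, nrow(image), ncol(image)),
              channel = NA_character_, steps = "otsu", threshold = thr)
}

# between-class-variance maximization over a weighted histogram;
# returns the level after which the split occurs (mask = value > threshold)
otsu_threshold <- function(levels, counts) {
  w <- counts / sum(counts)
  mu <- cumsum(w * levels)
  omega <- cumsum(w)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(levels) - 1L)   # split after level k
  sigma_b <- (mu_t * omega[k] - mu[k])^2 / (omega[k] * (1 - omega[k]))
  levels[k[which.max(sigma_b)]]
}

#' Construct a binary mask with provenance
#'
#' @param data Logical matrix.
#' @param channel Source channel name.
#' @param steps Character vector of processing steps applied.
#' @param threshold Optional numeric threshold recorded by [binarize_otsu()].
#' @return A logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(data, channel = NA_character_, steps = character(),
                        threshold = NULL) {
  stopifnot(is.matrix(data), is.logical(data))
  structure(data, class = c("binary_mask", "matrix", "array"),
            channel = channel, steps = steps, threshold = threshold)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", nrow(x), "x", ncol(x),
      "  foreground: ", sum(x),
      "  channel: ", attr(x, "channel"),
      "  steps: ", paste(attr(x, "steps"), collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' Discrete Euclidean disk structuring element
#'
#' Pixels at Euclidean distance at most `radius` from the centre pixel.
#'
#' @param radius Radius in pixels (>= 1).
#' @return 0/1 matrix of size `2*radius + 1`.
#' @export
disk_kernel <- function(radius) {
  stopifnot(radius >= 1)
  d <- seq(-floor(radius), floor(radius))
  k <- outer(d^2, d^2, `+`) <= radius^2
  storage.mode(k) <- "double"
  k
}

#' Morphological refinement of a binary mask
#'
#' Closing (dilate then erode) followed by opening (erode then dilate) with a
#' discrete Euclidean disk. Fills gaps and lumens narrower than the disk and
#' removes specks smaller than it. The compound close-then-open filter is
#' idempotent.
#'
#' @param mask Logical matrix (or `binary_mask`).
#' @param radius Disk radius in pixels (default 2, i.e. 1 um at 0.5 um/px).
#' @return A [binary_mask()] with updated provenance.
#' @export
morph_refine <- function(mask, radius = 2) {
  stopifnot(is.matrix(mask), is.logical(mask), radius >= 1)
  k <- disk_kernel(radius)
  x <- EBImage::Image(mask * 1)
  x <- EBImage::opening(EBImage::closing(x, k), k)
  binary_mask(EBImage::imageData(x) > 0.5,
              channel = attr(mask, "channel"),
              steps = c(attr(mask, "steps"),
                        sprintf("close_open_r%g", radius)),
              threshold = attr(mask, "threshold"))
}

#' Run the standard preprocessing chain on one channel
#'
#' smooth (9x9 mean) -> Otsu -> closing/opening, the chain applied
#' identically to every marker channel.
#'
#' @param image Numeric intensity matrix.
#' @param channel Channel name recorded in the mask provenance.
#' @param se_radius Structuring element radius for [morph_refine()].
#' @param smooth_size Averaging window size.
#' @return A refined [binary_mask()].
#' @export
preprocess_channel <- function(image, channel = NA_character_, se_radius = 2,
                               smooth_size = 9L) {
  sm <- smooth_channel(image, smooth_size)
  m <- binarize_otsu(sm)
  attr(m, "channel") <- channel
  attr(m, "steps") <- c(sprintf("smooth%dx%d", smooth_size, smooth_size),
                        "otsu")
  morph_refine(m, se_radius)
}

#' Preprocess every channel of a core
#'
#' Applies [preprocess_channel()] to each channel of a [channel_stack()] and
#' derives the tissue mask (union of all channel masks plus DAPI, followed by
#' closing with a large disk and hole filling).
#'
#' @param stack A [channel_stack()].
#' @param se_radius Structuring element radius for marker channels.
#' @param tissue_close_radius Disk radius (px) of the closing used to bridge
#'   nuclei when forming the tissue mask (default 25 px = 12.5 um).
#' @return A list with `masks` (named list of refined `binary_mask`s, one per
#'   channel), `tissue` and `epithelium` masks, and the input `stack` metadata.
#' @export
preprocess_stack <- function(stack, se_radius = 2, tissue_close_radius = 25) {
  stopifnot(inherits(stack, "channel_stack"))
  masks <- lapply(names(stack$channels), function(ch) {
    preprocess_channel(stack$channels[[ch]], channel = ch,
                       se_radius = se_radius)
  })
  names(masks) <- names(stack$channels)
  union_mask <- Reduce(`|`, masks)
  k <- disk_kernel(tissue_close_radius)
  tis <- EBImage::fillHull(EBImage::closing(EBImage::Image(union_mask * 1), k))
  tissue <- binary_mask(EBImage::imageData(tis) > 0.5,
                        channel = "all", steps = "union_close_fill")
  epi <- binary_mask(unclass(masks[["KRT"]]) & unclass(tissue),
                     channel = "KRT", steps = "krt_in_tissue")
  list(masks = masks, tissue = tissue, epithelium = epi,
       core_id = stack$core_id, batch_id = stack$batch_id,
       pixel_size = stack$pixel_size)
}

#' Core-level quality control
#'
#' Fails cores with too little detected tissue, too many saturated pixels, or
#' a core id present on the manual exclusion list (the proxy for pathologist
#' review of staining artifacts).
#'
#' @param stack A [channel_stack()].
#' @param min_tissue_mm2 Minimum tissue area (default 0.1 mm^2).
#' @param max_saturated_frac Maximum tolerated fraction of saturated pixels in
#'   any channel (default 0.05; saturation is >= 99.9% of the 16-bit ceiling).
#' @param exclusion_list Character vector of core ids to exclude.
#' @param tissue_mask Optional precomputed tissue mask (recomputed otherwise).
#' @return A one-row tibble: `core_id`, `pass`, `reasons` (list-column).
#' @export
qc_core <- function(stack, min_tissue_mm2 = 0.1, max_saturated_frac = 0.05,
                    exclusion_list = character(), tissue_mask = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  reasons <- character()
  if (stack$core_id %in% exclusion_list) {
    reasons <- c(reasons, "on exclusion list")
  }
  if (is.null(tissue_mask)) {
    tissue_mask <- preprocess_stack(stack)$tissue
  }
  area <- sum(tissue_mask) * stack$pixel_size^2 / 1e6
  if (area < min_tissue_mm2) {
    reasons <- c(reasons, "low tissue area")
  }
  sat <- vapply(stack$channels,
                function(ch) mean(ch >= 0.999 * 65535), numeric(1))
  if (any(sat > max_saturated_frac)) {
    reasons <- c(reasons, "saturated pixels")
  }
  tibble::tibble(core_id = stack$core_id, pass = length(reasons) == 0L,
                 tissue_mm2 = area, reasons = list(reasons))
}

#' Per-batch channel intensity report
#'
#' Summarizes median intensity per channel within each staining batch (TMA
#' section) and flags batches whose median deviates from the grand median by
#' more than `max_fold` in either direction — a light-weight check that marker
#' intensities are consistent across sections.
#'
#' @param stacks List of [channel_stack()] objects.
#' @param max_fold Fold-change flag threshold (default 2).
#' @return Tibble with `batch_id`, `channel`, `median`, `mad`, `grand_median`,
#'   `fold`, `flagged`.
#' @export
batch_intensity_report <- function(stacks, max_fold = 2) {
  stopifnot(length(stacks) >= 1L)
  per <- purrr::map_dfr(stacks, function(s) {
    tibble::tibble(
      batch_id = s$batch_id,
      channel = names(s$channels),
      median = vapply(s$channels, function(ch) stats::median(ch), numeric(1)),
      mad = vapply(s$channels, function(ch) stats::mad(ch), numeric(1))
    )
  })
  out <- per |>
    dplyr::group_by(.data$batch_id, .data$channel) |>
    dplyr::summarise(median = stats::median(.data$median),
                     mad = stats::median(.data$mad), .groups = "drop") |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(grand_median = stats::median(.data$median)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fold = ifelse(.data$grand_median > 0,
                    .data$median / .data$grand_median, 1),
      flagged = .data$fold > max_fold | .data$fold < 1 / max_fold
    )
  out
}
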