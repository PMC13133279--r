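#' Image simulator configuration
#'
#' Defines the study conditions emulated by the core-image generator:
#' spectrally unmixed 8-channel TMA core fields containing CD34+ vessels of
#' four morphological archetypes with planted marker-positivity rates and
#' KRT+ epithelial regions.
#'
#' @param image_size Pixels per side (default 1600).
#' @param pixel_size Micrometres per pixel side (default 0.5).
#' @param class_mixture Named proportions over the four morphology classes
#'   (default micro 0.49, collapsed 0.18, patent 0.14, irregular 0.18).
#' @param marker_rates Named per-vessel positivity probabilities for the five
#'   auxiliary markers (default ACKR1 0.042, CD36 0.067, KDR 0.14,
#'   LAMB1 0.068, MADCAM1 0.014).
#' @param target_density Expected overall vessel density in vessels/mm^2
#'   (default 197).
#' @param epithelial_fraction Expected KRT+ fraction of tissue (default 0.4).
#' @param noise_sd Additive Gaussian intensity noise SD on the 16-bit scale
#'   (default 0: the reference conditions are noiseless).
#' @param background_level Autofluorescence-like offset (default 3000).
#' @param signal_level Marker signal level (default 30000, ten times the
#'   background so Otsu has a clear valley).
#' @param closing_radius Structuring-element radius (px) the downstream
#'   refinement is expected to use; patent lumen radii are planted 1-2 px
#'   below it so refined patent masks are filled (default 2).
#' @param min_gap Minimum clearance in px enforced between planted vessels
#'   (default 16) so smoothing-induced mask dilation cannot merge them.
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(image_size = 1600L,
                             pixel_size = 0.5,
                             class_mixture = c(micro = 0.49, collapsed = 0.18,
                                               patent = 0.14,
                                               irregular = 0.18) / 0.99,
                             marker_rates = c(ACKR1 = 0.042, CD36 = 0.067,
                                              KDR = 0.14, LAMB1 = 0.068,
                                              MADCAM1 = 0.014),
                             target_density = 197,
                             epithelial_fraction = 0.4,
                             noise_sd = 0,
                             background_level = 3000,
                             signal_level = 30000,
                             closing_radius = 2,
                             min_gap = 16,
                             seed = NULL) {
  stopifnot(image_size > 0, pixel_size > 0, target_density >= 0,
            epithelial_fraction >= 0, epithelial_fraction < 1,
            noise_sd >= 0, background_level >= 0,
            signal_level > background_level)
  if (abs(sum(class_mixture) - 1) > 1e-9) {
    stop("class_mixture must sum to 1")
  }
  if (!setequal(names(class_mixture), VESSEL_CLASSES)) {
    stop("class_mixture must be named over: ",
         paste(VESSEL_CLASSES, collapse = ", "))
  }
  if (!setequal(names(marker_rates), AUX_MARKERS)) {
    stop("marker_rates must be named over: ",
         paste(AUX_MARKERS, collapse = ", "))
  }
  if (any(marker_rates < 0 | marker_rates > 1)) {
    stop("marker_rates must lie in [0, 1]")
  }
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 class_mixture = class_mixture[VESSEL_CLASSES],
                 marker_rates = marker_rates[AUX_MARKERS],
                 target_density = target_density,
                 epithelial_fraction = epithelial_fraction,
                 noise_sd = noise_sd, background_level = background_level,
                 signal_level = signal_level, closing_radius = closing_radius,
                 min_gap = min_gap, seed = seed),
            class = "image_sim_config")
}

#' Generate one vessel mask of a given morphological archetype
#'
#' Archetypes (sizes in pixels at 0.5 um/px):
#' * `micro`: filled near-circular blob, equivalent diameter 8-20 px
#'   (4-10 um), aspect at most 1.25 — solid and round. (Blobs under 4 um
#'   do not survive the 9x9 averaging filter of the downstream pipeline at
#'   0.5 um/px, so the planted range starts where recovery is exact.)
#' * `collapsed`: thin elongated capsule (length 40-90, width 6-9 px) —
#'   eccentricity above 0.95 by construction.
#' * `patent`: thick-walled disk of outer radius 11-17 px whose small
#'   central lumen (radius 1-2 px below `closing_radius`) is filled by the
#'   downstream closing.
#' * `irregular`: union of 2-4 overlapping bent elongated lobes radiating
#'   from a common hub.
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param class_label One of [VESSEL_CLASSES].
#' @param closing_radius Planted patent-lumen reference radius (default 2).
#' @return Logical matrix (tight bounding box) containing one connected mask.
#' @export
generate_vessel_shape <- function(class_label, closing_radius = 2) {
  switch(
    class_label,
    micro = {
      d <- stats::runif(1, 8, 20)
      aspect <- stats::runif(1, 1, 1.25)
      raster_ellipse(a = d / 2 * sqrt(aspect), b = d / 2 / sqrt(aspect),
                     theta = stats::runif(1, 0, pi))
    },
    collapsed = {
      len <- stats::runif(1, 40, 90)
      wid <- stats::runif(1, 6, 9)
      raster_capsule(len, wid, theta = stats::runif(1, 0, pi))
    },
    patent = {
      r_out <- stats::runif(1, 11, 17)
      lumen <- max(closing_radius - sample(1:2, 1L), 0)
      aspect <- stats::runif(1, 1, 1.15)
      raster_ellipse(a = r_out * sqrt(aspect), b = r_out / sqrt(aspect),
                     theta = stats::runif(1, 0, pi), lumen = lumen)
    },
    irregular = {
      n_lobes <- sample(2:4, 1L)
      masks <- lapply(seq_len(n_lobes), function(i) {
        raster_bent_capsule(len = stats::runif(1, 30, 60),
                            wid = stats::runif(1, 8, 14),
                            theta = stats::runif(1, 0, 2 * pi),
                            bend = stats::runif(1, -0.7, 0.7))
      })
      union_shapes(masks)
    },
    stop("unknown vessel class label: '", class_label, "'")
  )
}

# filled (optionally annular) rotated ellipse on a tight grid
raster_ellipse <- function(a, b, theta, lumen = 0) {
  half <- ceiling(max(a, b)) + 1L
  d <- seq(-half, half)
  x <- matrix(d, length(d), length(d), byrow = TRUE)
  y <- matrix(d, length(d), length(d))
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  m <- (u / a)^2 + (v / b)^2 <= 1
  if (lumen > 0) m <- m & (x^2 + y^2 > lumen^2)
  trim_mask(m)
}

# capsule: points within wid/2 of a centred segment of given length
raster_capsule <- function(len, wid, theta) {
  half <- ceiling(len / 2 + wid) + 1L
  d <- seq(-half, half)
  x <- matrix(d, length(d), length(d), byrow = TRUE)
  y <- matrix(d, length(d), length(d))
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  du <- pmax(abs(u) - len / 2, 0)
  trim_mask(du^2 + v^2 <= (wid / 2)^2)
}

# two joined capsule segments with an angle change at the knee
raster_bent_capsule <- function(len, wid, theta, bend) {
  half <- ceiling(len + wid) + 2L
  d <- seq(-half, half)
  x <- matrix(d, length(d), length(d), byrow = TRUE)
  y <- matrix(d, length(d), length(d))
  seg_dist2 <- function(px, py, x1, y1, x2, y2) {
    vx <- x2 - x1; vy <- y2 - y1
    t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2), 0), 1)
    (px - x1 - t * vx)^2 + (py - y1 - t * vy)^2
  }
  hx <- len / 2 * cos(theta); hy <- len / 2 * sin(theta)
  kx <- len / 2 * cos(theta + bend); ky <- len / 2 * sin(theta + bend)
  m <- seg_dist2(x, y, 0, 0, hx, hy) <= (wid / 2)^2 |
    seg_dist2(x, y, 0, 0, -kx, -ky) <= (wid / 2)^2
  trim_mask(m)
}

# overlay lobe masks centred on a common hub; result is connected
union_shapes <- function(masks) {
  hs <- vapply(masks, function(m) max(dim(m)), integer(1))
  side <- max(hs) + 2L
  if (side %% 2L == 0L) side <- side + 1L
  out <- matrix(FALSE, side, side)
  ctr <- (side + 1L) %/% 2L
  for (m in masks) {
    r0 <- ctr - (nrow(m) + 1L) %/% 2L
    c0 <- ctr - (ncol(m) + 1L) %/% 2L
    rr <- seq_len(nrow(m)) + r0
    cc <- seq_len(ncol(m)) + c0
    out[rr, cc] <- out[rr, cc] | m
  }
  trim_mask(out)
}

trim_mask <- function(m) {
  rs <- range(which(rowSums(m) > 0))
  cs <- range(which(colSums(m) > 0))
  m[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
}

#' Generate one simulated multiplex core image with ground truth
#'
#' Composes a fully tissue-covered core field: KRT+ epithelial blobs covering
#' `epithelial_fraction` of the field, DAPI nuclei throughout, and
#' Poisson(`target_density` x tissue area) CD34+ vessels rejection-placed in
#' the stroma with no overlaps and a minimum clearance. Each vessel is
#' painted positive for each auxiliary marker independently with
#' `marker_rates`; positive vessels carry one contiguous marker patch
#' covering well over 5% of the vessel area, negative vessels carry none.
#' A uniform autofluorescence-like background and optional Gaussian noise are
#' added to every channel.
#'
#' @param config An [image_sim_config()].
#' @param core_id,batch_id Identifiers stamped on the stack.
#' @return List with `stack` (a [channel_stack()]) and `truth` (class
#'   `vessel_ground_truth`: per-vessel records, integer label matrix,
#'   epithelium mask, planted parameters).
#' @export
generate_core_image <- function(config = image_sim_config(),
                                core_id = "core1", batch_id = "batch1") {
  stopifnot(inherits(config, "image_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$image_size
  bg <- config$background_level
  sig <- config$signal_level

  epi <- simulate_epithelium(n, config$epithelial_fraction)
  # keep vessels clear of the (blurred) epithelial boundary
  epi_buf <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(epi * 1), disk_kernel(6))) > 0.5

  tissue_mm2 <- n^2 * config$pixel_size^2 / 1e6
  n_vessels <- stats::rpois(1, config$target_density * tissue_mm2)
  classes <- if (n_vessels > 0) {
    sample(VESSEL_CLASSES, n_vessels, replace = TRUE,
           prob = config$class_mixture)
  } else character()

  label <- matrix(0L, n, n)
  occupied <- matrix(FALSE, n, n)
  records <- vector("list", n_vessels)
  gap <- config$min_gap
  for (i in seq_len(n_vessels)) {
    shape <- generate_vessel_shape(classes[i], config$closing_radius)
    placed <- FALSE
    for (try in seq_len(300L)) {
      r0 <- sample.int(n - nrow(shape) - 2L * gap, 1L) + gap
      c0 <- sample.int(n - ncol(shape) - 2L * gap, 1L) + gap
      rr <- seq_len(nrow(shape)) + r0 - 1L
      cc <- seq_len(ncol(shape)) + c0 - 1L
      box_r <- max(1L, r0 - gap):min(n, r0 + nrow(shape) - 1L + gap)
      box_c <- max(1L, c0 - gap):min(n, c0 + ncol(shape) - 1L + gap)
      if (any(occupied[box_r, box_c])) next
      if (any(epi_buf[rr, cc][shape])) next
      label[rr, cc][shape] <- i
      occupied[rr, cc] <- occupied[rr, cc] | shape
      px <- which(shape, arr.ind = TRUE)
      records[[i]] <- list(
        vessel_id = i, class = classes[i],
        pixels = cbind(row = px[, 1L] + r0 - 1L, col = px[, 2L] + c0 - 1L))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place vessel ", i, " of ", n_vessels,
           ": target_density too high for the image size")
    }
  }

  # marker positivity and patch painting
  marker_px <- lapply(AUX_MARKERS, function(mk) NULL)
  names(marker_px) <- AUX_MARKERS
  flags <- matrix(FALSE, n_vessels, length(AUX_MARKERS),
                  dimnames = list(NULL, AUX_MARKERS))
  for (mk in AUX_MARKERS) {
    pos <- stats::runif(n_vessels) < config$marker_rates[[mk]]
    flags[, mk] <- pos
    if (any(pos)) {
      marker_px[[mk]] <- do.call(rbind, lapply(which(pos), function(i) {
        marker_patch(records[[i]]$pixels)
      }))
    }
  }

  channels <- make_channels(n, bg, sig, epi, label, marker_px,
                            config$noise_sd)
  stack <- channel_stack(channels, pixel_size = config$pixel_size,
                         core_id = core_id, batch_id = batch_id)
  vessels <- tibble::tibble(
    vessel_id = seq_len(n_vessels),
    class = classes,
    area_px = vapply(records, function(r) nrow(r$pixels), integer(1)),
    centroid_x_um = vapply(records, function(r) mean(r$pixels[, "col"]),
                           numeric(1)) * config$pixel_size,
    centroid_y_um = vapply(records, function(r) mean(r$pixels[, "row"]),
                           numeric(1)) * config$pixel_size,
    pixels = lapply(records, `[[`, "pixels")
  )
  for (mk in AUX_MARKERS) vessels[[paste0(mk, "_pos")]] <- flags[, mk]
  truth <- structure(
    list(vessels = vessels, label = label, epithelium = epi,
         tissue_mm2 = tissue_mm2, config = config, core_id = core_id),
    class = "vessel_ground_truth")
  list(stack = stack, truth = truth)
}

# one contiguous patch: the k pixels nearest a random seed pixel,
# k = clamp(frac * area, >= 40 px so the patch survives the 9x9-filter +
# Otsu chain, <= the whole vessel)
marker_patch <- function(pixels) {
  area <- nrow(pixels)
  k <- round(stats::runif(1, 0.4, 0.9) * area)
  k <- min(max(k, 40L), area)
  s <- pixels[sample.int(area, 1L), ]
  d <- (pixels[, 1L] - s[1L])^2 + (pixels[, 2L] - s[2L])^2
  pixels[order(d)[seq_len(k)], , drop = FALSE]
}

# random elliptical blobs until the target cover fraction is reached
simulate_epithelium <- function(n, target_fraction) {
  epi <- matrix(FALSE, n, n)
  if (target_fraction <= 0) return(epi)
  goal <- target_fraction * n^2
  guard <- 0L
  while (sum(epi) < goal && guard < 500L) {
    guard <- guard + 1L
    a <- stats::runif(1, n / 16, n / 6.4)   # blob size scales with the field
    b <- a / stats::runif(1, 1, 2)
    blob <- raster_ellipse(a, b, theta = stats::runif(1, 0, pi))
    r0 <- sample.int(n, 1L) - nrow(blob) %/% 2L
    c0 <- sample.int(n, 1L) - ncol(blob) %/% 2L
    rr <- seq_len(nrow(blob)) + r0 - 1L
    cc <- seq_len(ncol(blob)) + c0 - 1L
    keep_r <- rr >= 1L & rr <= n
    keep_c <- cc >= 1L & cc <= n
    epi[rr[keep_r], cc[keep_c]] <-
      epi[rr[keep_r], cc[keep_c]] | blob[keep_r, keep_c]
  }
  epi
}

# paint all 8 channels; DAPI nuclei on a jittered grid guarantee that the
# tissue-mask closing can bridge them
make_channels <- function(n, bg, sig, epi, label, marker_px, noise_sd) {
  blank <- function() matrix(bg, n, n)
  channels <- list()
  # DAPI
  dapi <- blank()
  sp <- 12L
  gx <- seq(sp %/% 2L, n, by = sp)
  centers <- expand.grid(r = gx, c = gx)
  centers$r <- pmin(pmax(centers$r + sample(-4:4, nrow(centers), TRUE), 3L),
                    n - 2L)
  centers$c <- pmin(pmax(centers$c + sample(-4:4, nrow(centers), TRUE), 3L),
                    n - 2L)
  off <- which(disk_kernel(2.3) > 0, arr.ind = TRUE) - 3L
  nr <- rep(centers$r, each = nrow(off)) + off[, 1L]
  nc <- rep(centers$c, each = nrow(off)) + off[, 2L]
  dapi[cbind(nr, nc)] <- sig
  channels$DAPI <- dapi
  # auxiliary markers
  for (mk in AUX_MARKERS) {
    ch <- blank()
    if (!is.null(marker_px[[mk]])) ch[marker_px[[mk]]] <- sig
    channels[[mk]] <- ch
  }
  # CD34: all vessels
  cd34 <- blank()
  cd34[label > 0L] <- sig
  channels$CD34 <- cd34
  # KRT: epithelium
  krt <- blank()
  krt[epi] <- sig
  channels$KRT <- krt
  if (noise_sd > 0) {
    channels <- lapply(channels, function(ch) {
      pmin(pmax(round(ch + stats::rnorm(length(ch), 0, noise_sd)), 0), 65535)
    })
  }
  channels[PANEL_CHANNELS]
}

#' Simulate a batch of cores from one global seed
#'
#' The global seed is expanded into independent per-core substreams so cores
#' are reproducible individually and in any order.
#'
#' @param n_cores Number of cores.
#' @param config An [image_sim_config()] (its `seed` field is ignored here).
#' @param seed Global seed.
#' @param n_batches Number of staining batches (TMA sections) to cycle core
#'   assignments over (default 10).
#' @return List of `list(stack, truth)` pairs.
#' @export
simulate_cores <- function(n_cores, config = image_sim_config(), seed = 1L,
                           n_batches = 10L) {
  set.seed(seed)
  core_seeds <- sample.int(.Machine$integer.max - 1L, n_cores)
  lapply(seq_len(n_cores), function(i) {
    cfg <- config
    cfg$seed <- core_seeds[i]
    generate_core_image(cfg, core_id = sprintf("core%03d", i),
                        batch_id = sprintf("S%02d", (i - 1L) %% n_batches + 1L))
  })
}

#' Match extracted vessels to ground-truth vessels
#'
#' Each extracted vessel is assigned the ground-truth vessel whose planted
#' mask overlaps most of its pixels (ties broken toward the smaller id;
#' vessels overlapping no planted mask get `NA`).
#'
#' @param vessels Extracted vessel tibble (with `pixels` list-column).
#' @param truth A `vessel_ground_truth`.
#' @return `vessels` with `true_id` and `true_class` columns appended.
#' @export
match_ground_truth <- function(vessels, truth) {
  stopifnot(inherits(truth, "vessel_ground_truth"))
  lab <- truth$label
  ids <- vapply(vessels$pixels, function(px) {
    v <- lab[px]
    v <- v[v > 0L]
    if (length(v) == 0L) return(NA_integer_)
    tab <- tabulate(v)
    which.max(tab)
  }, integer(1))
  vessels$true_id <- ids
  vessels$true_class <- truth$vessels$class[ids]
  vessels
}

#' Write ground truth as JSON + a 16-bit label TIFF
#'
#' @param truth A `vessel_ground_truth`.
#' @param path Base path; writes `<path>.json` and `<path>_labels.tif`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "vessel_ground_truth"))
  v <- truth$vessels
  v$pixels <- NULL
  jsonlite::write_json(
    list(core_id = truth$core_id, tissue_mm2 = truth$tissue_mm2,
         vessels = v),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(truth$label / 65535, paste0(path, "_labels.tif"),
                  bits.per.sample = 16L)
  invisible(path)
}
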