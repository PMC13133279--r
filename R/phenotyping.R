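#' Phenotyping configuration
#'
#' @param marker_area_fraction_threshold Strict fraction of the vessel area a
#'   marker must exceed to call the vessel positive (default 0.05).
#' @param connectivity Pixel connectivity for vessel components, 4 or 8
#'   (default 8).
#' @param min_vessel_area_px Minimum component area kept, in pixels
#'   (default 12 px = 3 um^2 at 0.5 um/px).
#' @param pixel_size Pixel side length in micrometres (default 0.5).
#' @return A list of class `phenotyping_config`.
#' @export
phenotyping_config <- function(marker_area_fraction_threshold = 0.05,
                               connectivity = 8L,
                               min_vessel_area_px = 12L,
                               pixel_size = 0.5) {
  stopifnot(marker_area_fraction_threshold > 0,
            marker_area_fraction_threshold < 1,
            connectivity %in% c(4L, 8L),
            min_vessel_area_px >= 1)
  structure(list(marker_area_fraction_threshold = marker_area_fraction_threshold,
                 connectivity = as.integer(connectivity),
                 min_vessel_area_px = as.integer(min_vessel_area_px),
                 pixel_size = pixel_size),
            class = "phenotyping_config")
}

#' Label connected components of a binary mask
#'
#' 4-connectivity uses `EBImage::bwlabel` directly; 8-connectivity
#' additionally merges labels that touch diagonally (union-find over the
#' label adjacency graph). Labels are then renumbered so that ids follow the
#' row-major position of each component's first pixel, making ids
#' deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(lab) <- "integer"
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonally adjacent label pairs
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # NW-SE
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # NE-SW
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(max(lab))
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  relabel_rowmajor(lab)
}

# renumber labels 1..K by row-major order of each component's first pixel
relabel_rowmajor <- function(lab) {
  if (max(lab) == 0L) return(lab)
  nr <- nrow(lab)
  fg <- which(lab > 0L)
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  rowmajor <- (rows - 1L) * ncol(lab) + cols
  first <- tapply(rowmajor, lab[fg], min)
  ord <- order(first)
  remap <- integer(max(lab))
  remap[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[fg] <- remap[lab[fg]]
  lab
}

#' Core, epithelial, and stromal areas
#'
#' Areas in mm^2 from pixel counts; the epithelial mask is intersected with
#' the tissue mask, and the stromal area is the core area minus the
#' epithelial area (exactly, by construction).
#'
#' @param tissue_mask,krt_mask Logical matrices of identical shape.
#' @param pixel_size Pixel side in micrometres (default 0.5, i.e.
#'   0.25 um^2/px).
#' @return One-row tibble: `core_mm2`, `epithelial_mm2`, `stromal_mm2`,
#'   `flagged` (TRUE when the tissue area is zero and densities are
#'   undefined).
#' @export
compute_core_areas <- function(tissue_mask, krt_mask, pixel_size = 0.5) {
  stopifnot(all(dim(tissue_mask) == dim(krt_mask)))
  px_mm2 <- pixel_size^2 / 1e6
  core <- sum(tissue_mask) * px_mm2
  epi <- sum(krt_mask & tissue_mask) * px_mm2
  tibble::tibble(core_mm2 = core, epithelial_mm2 = epi,
                 stromal_mm2 = core - epi, flagged = core == 0)
}

#' Extract CD34+ vessel objects from a refined mask
#'
#' Connected components of the CD34 mask under the configured connectivity;
#' components smaller than `min_vessel_area_px` are discarded. Vessel ids are
#' assigned in row-major order of each component's first pixel, so extraction
#' is fully deterministic.
#'
#' @param cd34_mask Logical matrix (refined CD34 mask).
#' @param config A [phenotyping_config()].
#' @param core_id Core identifier stamped on each vessel row.
#' @return Tibble with `vessel_id`, `core_id`, `area_px`, `centroid_x_um`,
#'   `centroid_y_um`, and a `pixels` list-column of (row, col) matrices.
#' @export
extract_vessels <- function(cd34_mask, config = phenotyping_config(),
                            core_id = "core") {
  lab <- label_components(cd34_mask, config$connectivity)
  k <- max(lab)
  if (k == 0L) return(empty_vessel_table())
  fg <- which(lab > 0L)
  nr <- nrow(lab)
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  labs <- lab[fg]
  keep <- which(tabulate(labs, k) >= config$min_vessel_area_px)
  if (length(keep) == 0L) return(empty_vessel_table())
  ord <- order(labs)
  rows <- rows[ord]; cols <- cols[ord]; labs <- labs[ord]
  px_split <- split(seq_along(labs), labs)[as.character(keep)]
  pixels <- unname(lapply(px_split,
                          function(ii) cbind(row = rows[ii], col = cols[ii])))
  tibble::tibble(
    vessel_id = seq_along(keep),
    core_id = core_id,
    area_px = unname(vapply(pixels, nrow, integer(1))),
    centroid_x_um = vapply(pixels, function(p) mean(p[, 2L]), numeric(1)) *
      config$pixel_size,
    centroid_y_um = vapply(pixels, function(p) mean(p[, 1L]), numeric(1)) *
      config$pixel_size,
    pixels = unname(pixels)
  )
}

empty_vessel_table <- function() {
  tibble::tibble(vessel_id = integer(), core_id = character(),
                 area_px = integer(), centroid_x_um = numeric(),
                 centroid_y_um = numeric(), pixels = list())
}

#' Assign marker positivity flags to vessels
#'
#' A vessel is positive for a marker when the marker mask covers strictly
#' more than `marker_area_fraction_threshold` (default 5%) of the vessel
#' area.
#'
#' @param vessels Vessel tibble from [extract_vessels()].
#' @param marker_masks Named list of logical matrices (one per marker in
#'   [AUX_MARKERS]), preprocessed with the same chain as CD34.
#' @param config A [phenotyping_config()].
#' @return `vessels` with one logical column per marker (e.g. `ACKR1_pos`).
#' @export
assign_marker_flags <- function(vessels, marker_masks,
                                config = phenotyping_config()) {
  stopifnot(is.data.frame(vessels), is.list(marker_masks))
  thr <- config$marker_area_fraction_threshold
  for (mk in names(marker_masks)) {
    mm <- marker_masks[[mk]]
    frac <- vapply(vessels$pixels, function(p) {
      mean(mm[p])
    }, numeric(1))
    vessels[[paste0(mk, "_pos")]] <- frac > thr
  }
  vessels
}

#' Per-core vessel densities for the nine density variables
#'
#' Densities are counts per mm^2 of total core area: overall CD34+, the
#' morphology classes (collapsed, micro, patent, plus irregular), and the
#' five marker-positive categories. Stromal-normalized densities are emitted
#' as a secondary block (`*_stromal`).
#'
#' @param vessels Vessel tibble with marker flag columns and (optionally) a
#'   `morph_class` column.
#' @param areas One-row tibble from [compute_core_areas()].
#' @return One-row tibble of densities (`NA` when the core area is zero).
#' @export
vessel_densities <- function(vessels, areas) {
  stopifnot(is.data.frame(vessels), is.data.frame(areas), nrow(areas) == 1L)
  counts <- c(overall = nrow(vessels))
  for (cl in VESSEL_CLASSES) {
    counts[[cl]] <- if ("morph_class" %in% names(vessels)) {
      sum(vessels$morph_class == cl)
    } else NA_integer_
  }
  for (mk in AUX_MARKERS) {
    col <- paste0(mk, "_pos")
    counts[[mk]] <- if (col %in% names(vessels)) sum(vessels[[col]])
      else NA_integer_
  }
  dens <- function(n, a) if (a > 0) n / a else NA_real_
  out <- tibble::tibble(core_area_mm2 = areas$core_mm2)
  for (nm in names(counts)) out[[paste0("count_", nm)]] <- counts[[nm]]
  for (nm in names(counts)) {
    out[[paste0("density_", nm)]] <- dens(counts[[nm]], areas$core_mm2)
    out[[paste0("density_", nm, "_stromal")]] <-
      dens(counts[[nm]], areas$stromal_mm2)
  }
  out
}

#' Summarize one phenotyped core as a core record
#'
#' Bridges the image pipeline to the per-case aggregation: one row with
#' areas, category counts, densities and QC status, ready for
#' [aggregate_case_metrics()].
#'
#' @param phenotyped Output of [phenotype_core()].
#' @param case_id Case the core belongs to.
#' @param qc Optional one-row QC tibble from [qc_core()]; defaults to
#'   passing.
#' @return One-row tibble.
#' @export
core_record <- function(phenotyped, case_id, qc = NULL) {
  d <- vessel_densities(phenotyped$vessels, phenotyped$areas)
  tibble::tibble(core_id = phenotyped$core_id, case_id = case_id,
                 qc_pass = if (is.null(qc)) TRUE else qc$pass,
                 epithelial_mm2 = phenotyped$areas$epithelial_mm2,
                 stromal_mm2 = phenotyped$areas$stromal_mm2) |>
    dplyr::bind_cols(d)
}

#' Phenotype one core end to end
#'
#' Convenience wrapper: preprocess all channels, derive areas, extract CD34+
#' vessels, compute morphological features, and assign marker flags.
#'
#' @param stack A [channel_stack()].
#' @param config A [phenotyping_config()].
#' @param se_radius Structuring-element radius passed to
#'   [preprocess_stack()].
#' @return List with `vessels` (feature-annotated tibble), `areas`,
#'   `masks` (the preprocessing output), and `core_id`.
#' @export
phenotype_core <- function(stack, config = phenotyping_config(),
                           se_radius = 2) {
  pp <- preprocess_stack(stack, se_radius = se_radius)
  areas <- compute_core_areas(unclass(pp$tissue), unclass(pp$epithelium),
                              pixel_size = stack$pixel_size)
  vessels <- extract_vessels(unclass(pp$masks$CD34), config,
                             core_id = stack$core_id)
  if (nrow(vessels) > 0L) {
    vessels <- add_morph_features(vessels)
    vessels <- assign_marker_flags(
      vessels, lapply(pp$masks[AUX_MARKERS], unclass), config)
  }
  list(vessels = vessels, areas = areas, masks = pp, core_id = stack$core_id)
}
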