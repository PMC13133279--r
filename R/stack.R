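#' Channel order of the multiplex panel
#'
#' Fixed page order used for all multi-page TIFF I/O: nuclear stain first,
#' then the five auxiliary endothelial markers around CD34, then keratin.
#' @export
PANEL_CHANNELS <- c("DAPI", "ACKR1", "CD34", "CD36", "KDR", "LAMB1",
                    "MADCAM1", "KRT")

#' Endothelial markers scored by the >5% area rule
#' @export
AUX_MARKERS <- c("ACKR1", "CD36", "KDR", "LAMB1", "MADCAM1")

#' Vessel morphology classes (fixed documented order)
#' @export
VESSEL_CLASSES <- c("micro", "collapsed", "patent", "irregular")

#' One core's multi-channel image stack
#'
#' The unit of image processing: a named list of identically sized 2-D
#' intensity grids (16-bit scale, stored as numeric matrices) plus pixel-size
#' metadata and core/batch identifiers.
#'
#' @param channels Named list of numeric matrices; names must cover
#'   [PANEL_CHANNELS].
#' @param pixel_size Pixel side length in micrometres (default 0.5).
#' @param core_id,batch_id Identifiers.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size = 0.5, core_id = "core",
                          batch_id = "batch1") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  if (!all(PANEL_CHANNELS %in% names(channels))) {
    stop("channels must include: ", paste(PANEL_CHANNELS, collapse = ", "))
  }
  dims <- vapply(channels, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all channels must share dimensions")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(channels = channels[PANEL_CHANNELS],
                 pixel_size = pixel_size,
                 core_id = core_id, batch_id = batch_id),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<channel_stack> ", x$core_id, " (batch ", x$batch_id, "): ",
      d[1], "x", d[2], " px at ", x$pixel_size, " um/px, channels: ",
      paste(names(x$channels), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a channel stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages follow [PANEL_CHANNELS] order; intensities are written as 16-bit.
#' Pixel size and identifiers go into `<path>.json`.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_core_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  pages <- lapply(stack$channels, function(ch) {
    pmin(pmax(ch, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(core_id = stack$core_id, batch_id = stack$batch_id,
               pixel_size_um = stack$pixel_size,
               channels = names(stack$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a binary mask as a single-page TIFF with JSON provenance
#'
#' @param mask A [binary_mask()] (or logical matrix).
#' @param path Output TIFF path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(channel = attr(mask, "channel"), steps = attr(mask, "steps"),
         threshold = attr(mask, "threshold")),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a binary mask written by [write_mask_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @return A [binary_mask()].
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path) > 0.5
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  binary_mask(m, channel = if (is.null(meta$channel)) NA_character_
                           else meta$channel,
              steps = meta$steps %||% character(),
              threshold = meta$threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a channel stack written by [write_core_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @return A [channel_stack()].
#' @export
read_core_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  channels <- lapply(pages, function(p) round(p * 65535))
  names(channels) <- meta$channels
  channel_stack(channels, pixel_size = meta$pixel_size_um,
                core_id = meta$core_id, batch_id = meta$batch_id)
}
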