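#' Calibrated multi-channel image
#'
#' Container for a 2D multi-channel fluorescence image together with its
#' pixel-size calibration. The default calibration of 1/12 µm per pixel
#' matches a x100 oil-immersion objective where 12 pixels span 1 µm.
#'
#' Coordinate convention used throughout the package: 0-based `(row, col)`
#' pixel indices, a point sits at the pixel center, and physical distances
#' are obtained by multiplying pixel distances by `pixel_size_um`.
#'
#' @param pixels Integer array `height x width x n_channels` (a plain matrix
#'   is promoted to a single channel). Intensities must be non-negative.
#' @param pixel_size_um Microns per pixel; must be positive.
#' @param channel_names Character vector naming the channels; recycled or
#'   truncated to the number of channels. Defaults to the standard FISH
#'   layout: counterstain, telomere probe, whole-chromosome paint.
#' @return An object of class `calibrated_image`: a list with elements
#'   `pixels`, `pixel_size_um`, `channel_names`.
#' @export
calibrated_image <- function(pixels, pixel_size_um = 1 / 12,
                             channel_names = c("counterstain", "telomere", "paint")) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be a height x width x channel array", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  nc <- dim(pixels)[3L]
  channel_names <- rep_len(as.character(channel_names), nc)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_names = channel_names),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %d channel(s) [%s], %.5f um/px\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

#' Extract one channel as a matrix
#'
#' @param image A `calibrated_image`.
#' @param channel Channel name or index.
#' @return Numeric matrix of intensities.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "calibrated_image"))
  if (is.character(channel)) {
    i <- match(channel, image$channel_names)
    if (is.na(i)) stop(sprintf("no channel named '%s'", channel), call. = FALSE)
    channel <- i
  }
  image$pixels[, , channel]
}

#' Convert pixel lengths to microns
#'
#' Linear calibration: at the default 1/12 µm per pixel, 12 pixels equal
#' exactly 1 µm.
#'
#' @param length_px Length(s) in pixels, non-negative.
#' @param pixel_size_um Microns per pixel.
#' @return Length(s) in microns.
#' @export
px_to_um <- function(length_px, pixel_size_um = 1 / 12) {
  if (any(length_px < 0)) stop("`length_px` must be non-negative", call. = FALSE)
  length_px * pixel_size_um
}

#' Convert micron lengths to pixels
#'
#' Inverse of [px_to_um()].
#'
#' @inheritParams px_to_um
#' @param length_um Length(s) in microns, non-negative.
#' @return Length(s) in pixels.
#' @export
um_to_px <- function(length_um, pixel_size_um = 1 / 12) {
  if (any(length_um < 0)) stop("`length_um` must be non-negative", call. = FALSE)
  length_um / pixel_size_um
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated image to a multi-page TIFF
#'
#' Each channel becomes one 16-bit TIFF page (page order follows
#' `channel_names`); the calibration, channel names and optional seed are
#' stored in a JSON sidecar `<path>.json`. Integer intensities in
#' `[0, 65535]` round-trip exactly through [read_image()].
#'
#' @param image A `calibrated_image`.
#' @param path Output TIFF path.
#' @param seed Optional integer recorded in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, seed = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (any(px > 65535)) stop("intensities exceed 16-bit range", call. = FALSE)
  pages <- lapply(seq_len(dim(px)[3L]), function(k) round(px[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = image$pixel_size_um,
               channels = image$channel_names)
  if (!is.null(seed)) meta$seed <- seed
  # I(17) significant digits: doubles survive the JSON round trip exactly
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' Read a calibrated image from a multi-page TIFF
#'
#' Expects 1-4 pages of identical shape. Calibration and channel names are
#' taken from the JSON sidecar written by [write_image()]; if the sidecar is
#' absent the default calibration of 1/12 µm per pixel is applied and a
#' warning is emitted.
#'
#' @param path TIFF path.
#' @return A `calibrated_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L || length(pages) > 4L)
    stop(sprintf("expected 1-4 TIFF pages, got %d", length(pages)), call. = FALSE)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("TIFF pages differ in shape", call. = FALSE)
  if (length(dims[[1L]]) != 2L)
    stop("TIFF pages must be single-plane grayscale", call. = FALSE)
  px <- array(0, dim = c(dims[[1L]], length(pages)))
  for (k in seq_along(pages)) px[, , k] <- round(pages[[k]] * 65535)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    calibrated_image(px, pixel_size_um = meta$pixel_size_um,
                     channel_names = meta$channels)
  } else {
    warning(sprintf("no sidecar for %s; assuming 12 px per um", path),
            call. = FALSE)
    nm <- c("counterstain", "telomere", "paint", "extra")[seq_along(pages)]
    calibrated_image(px, pixel_size_um = 1 / 12, channel_names = nm)
  }
}
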