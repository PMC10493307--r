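# TIFF input/output for stacks and masks (via the tiff package) with a
# plain-text sidecar for the um/px calibration, plus CSV helpers.

.sidecar <- function(path) paste0(path, ".meta")

.read_pixel_size <- function(path) {
  sc <- .sidecar(path)
  if (file.exists(sc)) {
    ln <- grep("^pixel_size_um=", readLines(sc), value = TRUE)
    if (length(ln)) return(as.numeric(sub("^pixel_size_um=", "", ln[1])))
  }
  NULL
}

#' Read a TIFF image or z-stack
#'
#' Multi-page TIFFs become `(z, y, x)` stacks. The pixel size is read from
#' the TIFF resolution tag when present, else from the plain-text sidecar
#' `<path>.meta` written by [write_mask_tiff()]/[write_stack_tiff()]; an
#' explicit `pixel_size` always wins and is required for uncalibrated
#' third-party files.
#'
#' @param path TIFF file.
#' @param pixel_size um per pixel; overrides any metadata.
#' @param channel channel label for the result.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path, pixel_size = NULL, channel = "GFAP") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(pixel_size)) {
    inf <- attributes(pages[[1]])
    if (!is.null(inf$x.resolution) && inf$x.resolution > 0) {
      unit <- if (is.null(inf$resolution.unit)) "inch" else inf$resolution.unit
      um_per_unit <- switch(as.character(unit),
                            inch = 25400, cm = 10000, 10000)
      pixel_size <- um_per_unit / inf$x.resolution
    } else {
      pixel_size <- .read_pixel_size(path)
    }
    if (is.null(pixel_size))
      stop("no calibration for ", path,
           ": supply `pixel_size` explicitly")
  }
  mats <- lapply(pages, function(p) {
    m <- unclass(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]   # first channel
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  if (length(mats) == 1L)
    return(image_stack(mats[[1]], pixel_size = pixel_size,
                       channel = channel))
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (z in seq_along(mats)) arr[z, , ] <- mats[[z]]
  image_stack(arr, pixel_size = pixel_size, channel = channel)
}

.write_sidecar <- function(path, pixel_size)
  writeLines(sprintf("pixel_size_um=%.10g", pixel_size), .sidecar(path))

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' The calibration is stored in the `<path>.meta` sidecar.
#'
#' @param mask a [binary_mask()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(as.numeric(mask$pixels), nrow(mask$pixels))
  tiff::writeTIFF(img, path, bits.per.sample = 8L)
  .write_sidecar(path, mask$pixel_size)
  invisible(path)
}

#' Write an intensity stack as TIFF
#'
#' Intensities are scaled into `[0, 1]` over `max_intensity` and written
#' as 16-bit pages; the calibration goes to the `<path>.meta` sidecar.
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @param max_intensity full-scale intensity (default: image maximum).
#' @return The path, invisibly.
#' @export
write_stack_tiff <- function(stack, path, max_intensity = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (is.null(max_intensity)) max_intensity <- max(stack$data, 1)
  mats <- if (length(d) == 2L) list(stack$data / max_intensity)
  else lapply(seq_len(d[1]), function(z) stack$data[z, , ] / max_intensity)
  mats <- lapply(mats, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  .write_sidecar(path, stack$pixel_size)
  invisible(path)
}
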