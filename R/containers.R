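#' Calibrated intensity image or z-stack
#'
#' Wraps a 2D `(y, x)` matrix or 3D `(z, y, x)` array of non-negative
#' intensities together with its spatial calibration.
#'
#' @param data numeric matrix `(y, x)` or array `(z, y, x)`.
#' @param pixel_size in-plane pixel size in micrometres per pixel.
#' @param z_step spacing between z-slices in micrometres (default 1).
#' @param channel channel label, e.g. `"GFAP"`.
#' @return An `image_stack` object (list with `data`, `pixel_size`,
#'   `z_step`, `channel`).
#' @export
image_stack <- function(data, pixel_size, z_step = 1, channel = "GFAP") {
  if (!is.numeric(data) && !is.logical(data))
    stop("`data` must be numeric")
  d <- length(dim(data))
  if (is.null(dim(data)) || !(d %in% c(2L, 3L)))
    stop("`data` must be a 2D (y,x) matrix or 3D (z,y,x) array")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  if (any(data < 0)) stop("intensities must be non-negative")
  structure(
    list(data = data, pixel_size = pixel_size, z_step = z_step,
         channel = channel),
    class = "image_stack")
}

#' Calibrated binary mask
#'
#' @param pixels logical matrix `(y, x)`; `TRUE` is foreground.
#' @param pixel_size pixel size in micrometres per pixel.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (is.numeric(pixels)) pixels <- pixels != 0
  if (!is.logical(pixels) || length(dim(pixels)) != 2L)
    stop("`pixels` must be a logical (y,x) matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "binary_mask")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<image_stack> ", paste(d, collapse = " x "),
      sprintf(" | %.4g um/px | channel %s\n", x$pixel_size, x$channel))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d | %.4g um/px | %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton> %d px | %d endpoints, %d junction px | %.4g um/px\n",
    sum(x$pixels), sum(x$node_class == 1L), sum(x$node_class == 3L),
    x$pixel_size))
  invisible(x)
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat("<sholl_profile> radii", min(x$radii), "..", max(x$radii),
      "um | total", x$total, "\n")
  print(setNames(x$counts, x$radii))
  invisible(x)
}

as_mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) return(mask$pixels)
  if (is.logical(mask) && length(dim(mask)) == 2L) return(mask)
  stop("expected a `binary_mask` or logical matrix")
}
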