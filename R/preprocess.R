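#' Maximum-intensity projection of a z-stack
#'
#' Collapses a `(z, y, x)` stack to a single 2D image by taking, at every
#' `(y, x)` position, the maximum intensity over z. A 2D input is returned
#' unchanged, so the operation is idempotent.
#'
#' @param stack an [image_stack()].
#' @return A 2D `image_stack`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (length(d) == 2L) return(stack)
  if (d[1] < 1L) stop("stack has no z-slices")
  proj <- apply(stack$data, c(2L, 3L), max)
  image_stack(proj, pixel_size = stack$pixel_size, z_step = stack$z_step,
              channel = stack$channel)
}

#' Convert an image to 8-bit with a linear display window
#'
#' Maps `[display_min, display_max]` linearly onto `[0, 255]`, clipping
#' outside the window — the programmatic counterpart of setting
#' brightness/contrast before 8-bit conversion.
#'
#' @param image a 2D [image_stack()].
#' @param display_min,display_max intensity window; `display_min` maps to 0
#'   and `display_max` to 255. Defaults to the image range.
#' @return An 8-bit `image_stack` (integer values 0..255).
#' @export
to_8bit <- function(image, display_min = NULL, display_max = NULL) {
  stopifnot(inherits(image, "image_stack"))
  x <- image$data
  if (length(dim(x)) != 2L) stop("`to_8bit` expects a 2D image; project first")
  if (is.null(display_min)) display_min <- min(x)
  if (is.null(display_max)) display_max <- max(x)
  if (display_min >= display_max)
    stop("`display_min` must be strictly less than `display_max`")
  y <- (x - display_min) / (display_max - display_min) * 255
  y <- round(pmin(pmax(y, 0), 255))
  image_stack(y, pixel_size = image$pixel_size, z_step = image$z_step,
              channel = image$channel)
}

#' Otsu threshold level of an 8-bit image
#'
#' Maximizes between-class variance over the 256-bin histogram and returns
#' the first foreground level (pixels `>= level` are foreground), matching
#' the ImageJ convention.
#'
#' @param values integer vector or matrix of 8-bit intensities.
#' @return The threshold level (integer in 1..255).
#' @export
otsu_level <- function(values) {
  v <- as.integer(round(values))
  if (any(v < 0L | v > 255L)) stop("Otsu expects 8-bit values in 0..255")
  if (min(v) == max(v))
    stop("degenerate histogram: image is constant, Otsu threshold undefined")
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                      # count with value <= k
  m0 <- cumsum(h * lev)                # intensity sum with value <= k
  mt <- m0[256]
  w1 <- n - w0
  # between-class variance when splitting after bin k (fg = values > k)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv) - 1L             # background is 0..k
  k + 1L
}

#' Threshold an 8-bit image to a binary mask
#'
#' Segments the signal: foreground is every pixel at or above the chosen
#' level. The level is computed by Otsu's method by default or fixed
#' explicitly, and is always recorded on the result (attribute `"level"`)
#' and in the run log.
#'
#' @param image a 2D 8-bit [image_stack()].
#' @param method `"otsu"` or `"fixed"`.
#' @param level threshold level for `method = "fixed"`.
#' @param quiet suppress the level message.
#' @return A [binary_mask()] with attribute `"level"`.
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed"), level = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(image, "image_stack"))
  method <- match.arg(method)
  x <- image$data
  if (length(dim(x)) != 2L) stop("`threshold_mask` expects a 2D image")
  lev <- switch(method,
    otsu = otsu_level(x),
    fixed = {
      if (is.null(level)) stop("`level` is required for method = \"fixed\"")
      level
    })
  if (!quiet)
    message(sprintf("threshold: method=%s level=%d", method, as.integer(lev)))
  m <- binary_mask(x >= lev, pixel_size = image$pixel_size)
  attr(m, "level") <- as.integer(lev)
  attr(m, "method") <- method
  m
}

#' Despeckle (3x3 median filter)
#'
#' Removes salt-and-pepper noise with a 3x3 median filter using edge
#' replication at the borders — the behaviour of the ImageJ Despeckle
#' tool. Isolated foreground pixels are removed and isolated background
#' pixels inside solid foreground are filled; any pixel whose 3x3
#' neighbourhood is constant is untouched.
#'
#' @param x a [binary_mask()], [image_stack()] (2D) or numeric matrix.
#' @return The same type as the input, filtered.
#' @export
despeckle <- function(x) {
  if (inherits(x, "binary_mask")) {
    f <- .cpp_median3(matrix(as.numeric(x$pixels), nrow(x$pixels)))
    out <- binary_mask(f > 0.5, pixel_size = x$pixel_size)
    attr(out, "level") <- attr(x, "level")
    return(out)
  }
  if (inherits(x, "image_stack")) {
    if (length(dim(x$data)) != 2L) stop("`despeckle` expects a 2D image")
    return(image_stack(.cpp_median3(x$data), pixel_size = x$pixel_size,
                       z_step = x$z_step, channel = x$channel))
  }
  if (is.matrix(x)) return(.cpp_median3(x))
  stop("unsupported input to `despeckle`")
}
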