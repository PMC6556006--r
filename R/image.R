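#' Calibrated RGB brightfield image
#'
#' Bundles an 8-bit RGB pixel array with its physical pixel size. Brightfield
#' slide scans used throughout the package are assumed to be scanned at 20x
#' (0.5 um/pixel) unless stated otherwise.
#'
#' @param pixels Numeric array of dimension `H x W x 3`, intensities on the
#'   0-255 scale.
#' @param pixel_size_um Physical size of one pixel in micrometres (default
#'   0.5, i.e. a 20x scan).
#' @return An object of class `npq_image`: a list with elements `pixels` and
#'   `pixel_size_um`.
#' @examples
#' img <- rgb_image(array(255, dim = c(8, 8, 3)))
#' dim(img$pixels)
#' @export
rgb_image <- function(pixels, pixel_size_um = 0.5) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("Pixel intensities must lie in [0, 255].")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "npq_image")
}

#' @export
print.npq_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<npq_image> %d x %d px, %.3g um/pixel (%.3g x %.3g um)\n",
              d[1], d[2], x$pixel_size_um,
              d[2] * x$pixel_size_um, d[1] * x$pixel_size_um))
  invisible(x)
}

#' Read an RGB image from a PNG or TIFF file
#'
#' Thin wrapper over the png/tiff readers that rescales to the 0-255 range
#' and attaches the pixel size, which these formats do not reliably carry.
#'
#' @param path Path to an 8-bit RGB `.png`, `.tif` or `.tiff` file.
#' @inheritParams rgb_image
#' @return An [rgb_image()] object.
#' @export
read_rgb_image <- function(path, pixel_size_um = 0.5) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image extension '%s' (use png/tif/tiff).", ext))
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(raw * 255, pixel_size_um = pixel_size_um)
}

#' Write an RGB image to a PNG file
#'
#' @param image An [rgb_image()] object.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "npq_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Luminance (grayscale) map of an RGB image
#'
#' Rec. 601 luma weights; used for raw-intensity measurements such as the
#' relative immunointensity ratio.
#'
#' @param image An [rgb_image()] object.
#' @return A numeric `H x W` matrix on the 0-255 scale, carrying a
#'   `pixel_size_um` attribute.
#' @export
luminance <- function(image) {
  stopifnot(inherits(image, "npq_image"))
  p <- image$pixels
  out <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  attr(out, "pixel_size_um") <- image$pixel_size_um
  out
}

# Resolve a pixel size from a map attribute or explicit argument.
.pixel_size <- function(map, pixel_size_um = NULL) {
  ps <- pixel_size_um %||% attr(map, "pixel_size_um")
  if (is.null(ps)) {
    abort("No pixel size available: supply `pixel_size_um` or use a map derived from an `npq_image`.")
  }
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a
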