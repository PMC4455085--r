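#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}

# clamp to the representable 8-bit range
#' @noRd
clamp8 <- function(x) pmin(255, pmax(0, x))

#' Read an RGB image as an 8-bit array
#'
#' Loads a PNG file into the array convention used throughout the package:
#' `dim = c(height, width, 3)`, integer-valued channels in `[0, 255]`,
#' 0-based pixel coordinates with x increasing rightwards (columns) and
#' y downwards (rows). Grayscale PNGs are expanded to three equal channels.
#'
#' @param path Path to a PNG file.
#' @return A numeric array with `dim = c(height, width, 3)`.
#' @export
read_image_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  round(a * 255)
}

#' Write an 8-bit RGB array to PNG
#'
#' @param image Array `c(height, width, 3)` with values in `[0, 255]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' @noRd
check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("`image` must be an array with dim c(height, width, 3)")
  if (min(image) < 0 || max(image) > 255)
    stopf("`image` channel values must lie in [0, 255]")
  invisible(image)
}
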