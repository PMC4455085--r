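#' Geometric layout of a well plate in an image
#'
#' Maps well addresses (`"A1"` ... row letter + column number) to pixel
#' regions of interest. Pixel coordinates are 0-based, x rightwards, y
#' downwards; a pixel belongs to a well's circular ROI when its centre (its
#' integer coordinate) lies within `roi_radius` of the well centre.
#'
#' @param rows,cols Number of well rows and columns (8 x 12 for a 96-well
#'   plate).
#' @param origin Length-2 numeric, pixel coordinates `c(x, y)` of the centre
#'   of well A1.
#' @param pitch Centre-to-centre spacing in pixels; scalar or `c(x, y)`.
#' @param roi_radius ROI radius in pixels; must be smaller than half the
#'   pitch so neighbouring ROIs cannot touch.
#' @param width,height Image dimensions in pixels; defaults leave the same
#'   margin right/below as `origin` leaves left/above. Every ROI must lie
#'   fully inside the image.
#' @param well_map Optional named character vector mapping well address to a
#'   sample or calibration-level identity.
#' @return An object of class `plate_layout`.
#' @examples
#' plate_layout(rows = 2, cols = 3, origin = c(15, 15), pitch = 20, roi_radius = 7)
#' @export
plate_layout <- function(rows, cols, origin, pitch, roi_radius,
                         width = NULL, height = NULL, well_map = NULL) {
  if (length(pitch) == 1L) pitch <- c(pitch, pitch)
  stopifnot(length(origin) == 2L, length(pitch) == 2L)
  if (rows < 1 || cols < 1) stopf("`rows` and `cols` must be >= 1")
  if (roi_radius <= 0) stopf("`roi_radius` must be > 0")
  if (roi_radius >= min(pitch) / 2)
    stopf("`roi_radius` (%g) must be < pitch/2 (%g)", roi_radius, min(pitch) / 2)
  if (is.null(width))  width  <- ceiling(2 * origin[1] + (cols - 1) * pitch[1]) + 1
  if (is.null(height)) height <- ceiling(2 * origin[2] + (rows - 1) * pitch[2]) + 1
  lay <- structure(list(rows = rows, cols = cols, origin = origin,
                        pitch = pitch, roi_radius = roi_radius,
                        width = width, height = height, well_map = well_map),
                   class = "plate_layout")
  # every ROI fully inside the image
  last <- well_center(lay, well_address(rows, cols))
  if (origin[1] - roi_radius < 0 || origin[2] - roi_radius < 0 ||
      last[1] + roi_radius > width - 1 || last[2] + roi_radius > height - 1)
    stopf("well ROIs do not all lie inside the %d x %d image", width, height)
  lay
}

#' All well addresses of a layout, row-major
#' @param layout A [plate_layout()].
#' @return Character vector, e.g. `c("A1", "A2", ...)`.
#' @export
plate_wells <- function(layout) {
  as.vector(t(outer(seq_len(layout$rows), seq_len(layout$cols), well_address)))
}

#' @noRd
well_address <- function(row, col) paste0(LETTERS[row], col)

#' @noRd
parse_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Z])([0-9]+)$", well))[[1]]
  if (length(m) != 3L) stopf("malformed well address: '%s'", well)
  c(row = match(m[2], LETTERS), col = as.integer(m[3]))
}

#' Pixel coordinates of a well centre
#' @param layout A [plate_layout()].
#' @param well Well address, e.g. `"B3"`.
#' @return Numeric `c(x, y)`, 0-based pixel coordinates.
#' @export
well_center <- function(layout, well) {
  rc <- parse_well(well)
  if (rc["row"] > layout$rows || rc["col"] > layout$cols)
    stopf("well '%s' is outside the %d x %d layout", well, layout$rows, layout$cols)
  c(layout$origin[1] + (rc["col"] - 1) * layout$pitch[1],
    layout$origin[2] + (rc["row"] - 1) * layout$pitch[2])
}

# 0-based (x, y) pixel coordinates whose centres fall inside a disc
#' @noRd
disc_pixels <- function(center, radius, width = Inf, height = Inf) {
  xs <- max(0, floor(center[1] - radius)):min(width - 1, ceiling(center[1] + radius))
  ys <- max(0, floor(center[2] - radius)):min(height - 1, ceiling(center[2] + radius))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' @noRd
rvs_ratio <- function(a, b) {
  if (any(a + b == 0)) stopf("channel ratio undefined: channel sum is 0")
  (a - b) / (a + b)
}

#' Per-ROI colour metrics of one well
#'
#' Computes mean red/green/blue over the circular ROI and the normalised
#' channel-difference statistics used as colour-intensity proxies:
#' `rvsb = (R - B)/(R + B)` for the yellow of lumefantrine and
#' `rvsg = (R - G)/(R + G)` for the orange/red artemether reaction product.
#' Ratios are computed from the ROI-mean channels, not averaged per-pixel
#' ratios.
#'
#' @param image 8-bit RGB array, `dim = c(height, width, 3)`.
#' @param layout A [plate_layout()].
#' @param well Well address.
#' @return A one-row tibble: `well`, `n_pixels`, `mean_red`, `mean_green`,
#'   `mean_blue`, `rvsb`, `rvsg`.
#' @export
extract_well <- function(image, layout, well) {
  check_image(image)
  ctr <- well_center(layout, well)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (ctr[1] - layout$roi_radius < 0 || ctr[2] - layout$roi_radius < 0 ||
      ctr[1] + layout$roi_radius > w - 1 || ctr[2] + layout$roi_radius > h - 1)
    stopf("ROI of well '%s' extends outside the image", well)
  px <- disc_pixels(ctr, layout$roi_radius, w, h)
  if (nrow(px) == 0L) stopf("ROI of well '%s' contains no pixels", well)
  # array is [y + 1, x + 1, channel]
  idx_r <- cbind(px$y + 1L, px$x + 1L, 1L)
  idx_g <- cbind(px$y + 1L, px$x + 1L, 2L)
  idx_b <- cbind(px$y + 1L, px$x + 1L, 3L)
  mr <- mean(image[idx_r]); mg <- mean(image[idx_g]); mb <- mean(image[idx_b])
  tibble::tibble(well = well, n_pixels = nrow(px),
                 mean_red = mr, mean_green = mg, mean_blue = mb,
                 rvsb = rvs_ratio(mr, mb), rvsg = rvs_ratio(mr, mg))
}

#' Colour metrics for many wells of a plate image
#'
#' @inheritParams extract_well
#' @param wells Well addresses to measure; defaults to the names of
#'   `layout$well_map` if present, else every well of the layout.
#' @return A tibble with one [extract_well()] row per well, plus a `sample`
#'   column when the layout carries a `well_map`.
#' @export
measure_plate <- function(image, layout, wells = NULL) {
  if (is.null(wells))
    wells <- if (!is.null(layout$well_map)) names(layout$well_map) else plate_wells(layout)
  out <- do.call(rbind, lapply(wells, function(w) extract_well(image, layout, w)))
  if (!is.null(layout$well_map))
    out$sample <- unname(layout$well_map[out$well])
  out
}

#' Gray value of an RGB triple
#'
#' Weighted combination of the channels. The default equal weighting
#' (1/3, 1/3, 1/3) is the plain RGB mean (the common ImageJ default);
#' luma weights such as `c(0.299, 0.587, 0.114)` may be supplied instead.
#'
#' @param r,g,b Channel values; vectorised.
#' @param weights Non-negative length-3 weights summing to 1.
#' @return Numeric gray values.
#' @examples
#' gray_value(90, 180, 0)  # 90
#' @export
gray_value <- function(r, g, b, weights = c(1, 1, 1) / 3) {
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stopf("`weights` must be 3 non-negative values summing to 1")
  r * weights[1] + g * weights[2] + b * weights[3]
}

#' @noRd
gray_image <- function(image, weights = c(1, 1, 1) / 3) {
  gray_value(image[, , 1], image[, , 2], image[, , 3], weights)
}

#' Mean gray value over a disc ROI
#'
#' @param image 8-bit RGB array.
#' @param center Disc centre `c(x, y)`, 0-based pixels.
#' @param radius Disc radius in pixels.
#' @param weights Gray-conversion weights, see [gray_value()].
#' @return Mean gray value over pixels whose centres lie in the disc.
#' @export
disc_mean_gray <- function(image, center, radius, weights = c(1, 1, 1) / 3) {
  check_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- disc_pixels(center, radius, w, h)
  if (nrow(px) == 0L) stopf("disc ROI contains no pixels")
  gv <- gray_value(image[cbind(px$y + 1L, px$x + 1L, 1L)],
                   image[cbind(px$y + 1L, px$x + 1L, 2L)],
                   image[cbind(px$y + 1L, px$x + 1L, 3L)], weights)
  mean(gv)
}

#' Locate tablet discs in a fluorescence image
#'
#' Thresholds the gray image (Otsu's method by default — valid because the
#' generator guarantees a background strictly darker than every disc),
#' labels connected bright components, and fits each as a disc (centroid +
#' equivalent-area radius). Discs are returned row-major (top-to-bottom,
#' left-to-right within a row).
#'
#' @param image 8-bit RGB array.
#' @param expected_discs Optional count; an error is raised when the number
#'   of discs found differs.
#' @param threshold Gray-value threshold in `[0, 255]`; `NULL` uses Otsu's
#'   method (via EBImage).
#' @param min_area Components smaller than this many pixels are discarded as
#'   specks.
#' @return A tibble with columns `x`, `y` (centroid, 0-based), `radius`,
#'   `area`.
#' @export
tablet_rois <- function(image, expected_discs = NULL, threshold = NULL,
                        min_area = 9) {
  check_image(image)
  g <- gray_image(image)
  if (is.null(threshold)) {
    if (max(g) - min(g) < 1) {
      lab <- array(0, dim(g))  # flat image: nothing to segment
    } else {
      thr <- EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1)) * 255
      lab <- EBImage::imageData(EBImage::bwlabel(g > thr))
    }
  } else {
    lab <- EBImage::imageData(EBImage::bwlabel(g > threshold))
  }
  n <- max(lab)
  discs <- list()
  for (k in seq_len(n)) {
    ind <- which(lab == k, arr.ind = TRUE)   # [ ,1] = y + 1, [ ,2] = x + 1
    if (nrow(ind) < min_area) next
    discs[[length(discs) + 1L]] <- tibble::tibble(
      x = mean(ind[, 2]) - 1, y = mean(ind[, 1]) - 1,
      radius = sqrt(nrow(ind) / pi), area = nrow(ind))
  }
  out <- if (length(discs)) do.call(rbind, discs) else
    tibble::tibble(x = numeric(), y = numeric(), radius = numeric(), area = numeric())
  if (!is.null(expected_discs) && nrow(out) != expected_discs)
    stopf("found %d disc(s), expected %d", nrow(out), expected_discs)
  if (nrow(out) > 1L) {
    # group into rows by vertical gaps larger than the typical radius
    o <- order(out$y)
    out <- out[o, ]
    row_id <- cumsum(c(1, diff(out$y) > median(out$radius)))
    out <- out[order(row_id, out$x), ]
  }
  out
}

#' Gray-value profile across a tablet diameter
#'
#' Samples gray values along the horizontal line through the disc centre,
#' spanning the disc plus a margin on each side (a plot of gray values
#' across the diameter of a tablet). The summary is the mean gray over the
#' full disc ROI, the per-tablet intensity used by the Tier II fluorescence
#' screen.
#'
#' @param image 8-bit RGB array.
#' @param center Disc centre `c(x, y)`, 0-based pixels.
#' @param radius Disc radius in pixels.
#' @param margin Extra pixels sampled on each flank.
#' @param weights Gray-conversion weights.
#' @return An object of class `intensity_profile`: list with `positions`
#'   (pixel offsets from the centre), `gray_values` (same length), and
#'   `summary` (mean disc gray value).
#' @export
diameter_profile <- function(image, center, radius, margin = 5,
                             weights = c(1, 1, 1) / 3) {
  check_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  half <- round(radius) + margin
  xs <- round(center[1]) + (-half):half
  yr <- round(center[2])
  if (min(xs) < 0 || max(xs) > w - 1 || yr < 0 || yr > h - 1)
    stopf("profile line extends outside the image")
  gv <- gray_value(image[cbind(yr + 1L, xs + 1L, 1L)],
                   image[cbind(yr + 1L, xs + 1L, 2L)],
                   image[cbind(yr + 1L, xs + 1L, 3L)], weights)
  structure(list(positions = xs - round(center[1]), gray_values = gv,
                 summary = disc_mean_gray(image, center, radius, weights)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("Diameter gray-value profile: %d samples, disc mean %.2f\n",
              length(x$positions), x$summary))
  invisible(x)
}
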