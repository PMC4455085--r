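#' Authentic fluorescence reference band (Tier II, CD-3)
#'
#' Authentic tablets produce consistent fluorescence intensities under UV
#' illumination; any deviation — brighter or darker — marks a suspected
#' counterfeit. The band is a control-chart-style interval centred on the
#' mean of the authentic reference intensities with halfwidth `k` sample
#' standard deviations.
#'
#' @param intensities Gray values of at least two authentic reference
#'   tablets.
#' @param k Halfwidth multiplier; the default 3 is the conventional
#'   control-chart band.
#' @return An object of class `reference_band`: list with `center`,
#'   `halfwidth`, `k`, `source_n`.
#' @examples
#' build_reference_band(c(148, 151, 150, 149), k = 3)
#' @export
build_reference_band <- function(intensities, k = 3) {
  if (!is.numeric(intensities) || length(intensities) < 2L)
    stopf("need at least 2 reference intensities to build a band")
  if (any(!is.finite(intensities))) stopf("reference intensities must be finite")
  assert_scalar_num(k, "k")
  if (k < 0) stopf("`k` must be >= 0")
  structure(list(center = mean(intensities),
                 halfwidth = k * sd(intensities),
                 k = k, source_n = length(intensities)),
            class = "reference_band")
}

#' @export
print.reference_band <- function(x, ...) {
  cat(sprintf("Fluorescence reference band: %.2f +/- %.2f (k = %g, n = %d)\n",
              x$center, x$halfwidth, x$k, x$source_n))
  invisible(x)
}

#' Tier II fluorescence screen against the reference band
#'
#' A sample passes when its mean gray value lies within the band; deviations
#' are classified by direction, since both abnormally bright tablets (e.g.
#' degraded or repackaged product) and abnormally dark ones are suspect.
#'
#' @param sample_intensity Mean disc gray value(s); vectorised.
#' @param band A [build_reference_band()] object.
#' @return Character vector in `{"pass", "fail-brighter", "fail-darker"}`.
#' @examples
#' band <- build_reference_band(c(148, 151, 150, 149))
#' cd3_screen(c(150, 190, 110), band)
#' @export
cd3_screen <- function(sample_intensity, band) {
  if (!inherits(band, "reference_band")) stopf("`band` must be a reference_band")
  dev <- sample_intensity - band$center
  ifelse(abs(dev) <= band$halfwidth, "pass",
         ifelse(dev > 0, "fail-brighter", "fail-darker"))
}
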