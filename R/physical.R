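#' Tablet specification limits (Tier I)
#'
#' Closed acceptance intervals for tablet weight, diameter and thickness.
#' The defaults are the specification ranges for an authentic Coartem
#' (artemether-lumefantrine 20/120 mg) tablet: weight 0.228--0.252 g and
#' thickness 3.0--3.4 mm per the manufacturer, diameter 9.1--9.2 mm as
#' determined from measurements of 12 authentic tablets. Endpoints are
#' inclusive: a tablet measuring exactly 9.2 mm passes.
#'
#' @param weight_g Length-2 numeric, weight interval in grams.
#' @param diameter_mm Length-2 numeric, diameter interval in millimetres.
#' @param thickness_mm Length-2 numeric, thickness interval in millimetres.
#' @return An object of class `spec_limits`.
#' @examples
#' spec_limits()
#' @export
spec_limits <- function(weight_g = c(0.228, 0.252),
                        diameter_mm = c(9.1, 9.2),
                        thickness_mm = c(3.0, 3.4)) {
  for (nm in c("weight_g", "diameter_mm", "thickness_mm")) {
    iv <- get(nm)
    if (!is.numeric(iv) || length(iv) != 2L || any(!is.finite(iv)))
      stopf("`%s` must be a length-2 finite numeric interval", nm)
    if (iv[1] > iv[2]) stopf("`%s` must satisfy min <= max", nm)
    if (any(iv <= 0)) stopf("`%s` bounds must be > 0", nm)
  }
  structure(list(weight_g = weight_g, diameter_mm = diameter_mm,
                 thickness_mm = thickness_mm),
            class = "spec_limits")
}

#' @export
print.spec_limits <- function(x, ...) {
  cat("Tablet specification limits (closed intervals):\n")
  cat(sprintf("  weight    : %.3f - %.3f g\n", x$weight_g[1], x$weight_g[2]))
  cat(sprintf("  diameter  : %.2f - %.2f mm\n", x$diameter_mm[1], x$diameter_mm[2]))
  cat(sprintf("  thickness : %.2f - %.2f mm\n", x$thickness_mm[1], x$thickness_mm[2]))
  invisible(x)
}

#' Is a measurement inside a closed interval?
#'
#' Endpoints are inclusive. Vectorised over `value`.
#'
#' @param value Numeric measurements.
#' @param interval Length-2 numeric `c(min, max)` with `min <= max`.
#' @return Logical vector.
#' @examples
#' in_range(0.228, c(0.228, 0.252))  # TRUE, boundary is inclusive
#' in_range(0.306, c(0.228, 0.252))  # FALSE
#' @export
in_range <- function(value, interval) {
  if (!is.numeric(interval) || length(interval) != 2L || interval[1] > interval[2])
    stopf("`interval` must be numeric c(min, max) with min <= max")
  value >= interval[1] & value <= interval[2]
}

#' Tier I screen: tablet measurements against specification ranges
#'
#' Each tablet passes only if weight, diameter and thickness all fall inside
#' their (closed) specification intervals; a single out-of-range measurement
#' fails the tablet.
#'
#' @param tablets A data frame with columns `sample_id`, `weight_g`,
#'   `diameter_mm`, `thickness_mm` (see [read_tablets()]).
#' @param spec A [spec_limits()] object.
#' @return A tibble with one row per tablet: `sample_id`, logical flags
#'   `weight_ok`, `diameter_ok`, `thickness_ok`, and `verdict`
#'   (`"pass"`/`"fail"`).
#' @examples
#' t <- tibble::tibble(sample_id = "CF2", weight_g = 0.241,
#'                     diameter_mm = 9.2, thickness_mm = 3.2)
#' screen_tablets(t)
#' @export
screen_tablets <- function(tablets, spec = spec_limits()) {
  if (!inherits(spec, "spec_limits")) stopf("`spec` must be a spec_limits object")
  need <- c("sample_id", "weight_g", "diameter_mm", "thickness_mm")
  miss <- setdiff(need, names(tablets))
  if (length(miss)) stopf("`tablets` is missing column(s): %s", paste(miss, collapse = ", "))
  m <- tablets[c("weight_g", "diameter_mm", "thickness_mm")]
  if (any(vapply(m, function(x) any(!is.finite(x) | x <= 0), logical(1))))
    stopf("all tablet measurements must be finite and > 0")
  wok <- in_range(tablets$weight_g, spec$weight_g)
  dok <- in_range(tablets$diameter_mm, spec$diameter_mm)
  tok <- in_range(tablets$thickness_mm, spec$thickness_mm)
  tibble::tibble(
    sample_id = as.character(tablets$sample_id),
    weight_ok = wok, diameter_ok = dok, thickness_ok = tok,
    verdict = ifelse(wok & dok & tok, "pass", "fail")
  )
}

#' Tier I screen for a single tablet
#'
#' @param sample_id Sample identifier.
#' @param weight_g Weight in grams.
#' @param diameter_mm Diameter in millimetres.
#' @param thickness_mm Thickness in millimetres.
#' @inheritParams screen_tablets
#' @return A one-row tibble as in [screen_tablets()].
#' @export
screen_tablet <- function(sample_id, weight_g, diameter_mm, thickness_mm,
                          spec = spec_limits()) {
  screen_tablets(tibble::tibble(sample_id = sample_id, weight_g = weight_g,
                                diameter_mm = diameter_mm,
                                thickness_mm = thickness_mm), spec)
}

#' Read a tablet-measurement CSV
#'
#' The file must declare its weight unit in the header: exactly one of
#' `weight_g` (grams) or `weight_mg` (milligrams). Milligram weights are
#' converted to grams on load; the unit is never guessed, because a silent
#' grams/milligrams mix-up is the most likely real-world failure when
#' specification tables print grams but balances print milligrams.
#'
#' @param path Path to a CSV with columns `sample_id`, `weight_g` or
#'   `weight_mg`, `diameter_mm`, `thickness_mm`, optionally `label`.
#' @return A tibble with `weight_g` in grams.
#' @export
read_tablets <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  has_g <- "weight_g" %in% names(d)
  has_mg <- "weight_mg" %in% names(d)
  if (has_g == has_mg)
    stopf("measurement CSV must have exactly one of `weight_g` or `weight_mg` (got %s)",
          if (has_g) "both" else "neither")
  if (has_mg) {
    d$weight_g <- d$weight_mg / 1000
    d$weight_mg <- NULL
  }
  need <- c("sample_id", "weight_g", "diameter_mm", "thickness_mm")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("measurement CSV is missing column(s): %s",
                          paste(miss, collapse = ", "))
  keep <- intersect(c(need, "label"), names(d))
  tibble::as_tibble(d[keep])
}
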