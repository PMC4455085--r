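#' Calibration dilution-series design
#'
#' A fixed-dose AMLF tablet (lumefantrine 120 mg, artemether 20 mg) is
#' dissolved in 4 mL glacial acetic acid, so the 100% calibration level is
#' 30 mg/mL LF and 5 mg/mL AM; the series spans 120% down to 10% of the
#' label dose.
#'
#' @param dose_mg Named numeric, per-analyte label dose in mg;
#'   default `c(LF = 120, AM = 20)`.
#' @param volume_ml Dissolution volume in mL (default 4).
#' @param levels_pct Calibration levels as percent of label dose, each in
#'   `(0, 200]`; default `c(120, 100, 80, 50, 25, 10)`.
#' @return An object of class `dilution_design`.
#' @export
dilution_design <- function(dose_mg = c(LF = 120, AM = 20), volume_ml = 4,
                            levels_pct = c(120, 100, 80, 50, 25, 10)) {
  if (!is.numeric(dose_mg) || is.null(names(dose_mg)) || any(dose_mg <= 0))
    stopf("`dose_mg` must be a named numeric vector of positive doses")
  assert_scalar_num(volume_ml, "volume_ml", positive = TRUE)
  if (!is.numeric(levels_pct) || length(levels_pct) == 0 ||
      any(levels_pct <= 0 | levels_pct > 200))
    stopf("`levels_pct` must be percentages in (0, 200]")
  structure(list(dose_mg = dose_mg, volume_ml = volume_ml,
                 levels_pct = levels_pct),
            class = "dilution_design")
}

#' Concentrations of the calibration dilution series
#'
#' `concentration = (level_pct / 100) * dose_mg / volume_ml` for each analyte
#' and level — linear in level and dose, inverse in volume. With the default
#' design the LF series is 36, 30, 24, 15, 7.5, 3.0 mg/mL and the AM series
#' is 6, 5, 4, 2.5, 1.25, 0.5 mg/mL.
#'
#' @param design A [dilution_design()].
#' @return A tibble with columns `analyte`, `level_pct`, `concentration`
#'   (mg/mL).
#' @examples
#' design_dilution_series(dilution_design())
#' @export
design_dilution_series <- function(design = dilution_design()) {
  if (!inherits(design, "dilution_design")) stopf("`design` must be a dilution_design")
  out <- expand.grid(level_pct = design$levels_pct,
                     analyte = names(design$dose_mg),
                     stringsAsFactors = FALSE)
  out$concentration <- (out$level_pct / 100) *
    design$dose_mg[out$analyte] / design$volume_ml
  tibble::as_tibble(out[c("analyte", "level_pct", "concentration")])
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of a scalar response (RvsB, RvsG, or
#' absorbance) against concentration; `r_squared` is the squared Pearson
#' correlation. Constant responses are degenerate: the fit is flagged and
#' `r_squared` is defined as 0 with a warning.
#'
#' @param concentrations Numeric, at least 3 distinct values (mg/mL).
#' @param responses Numeric, same length.
#' @param analyte Optional label (`"LF"`, `"AM"`, ...).
#' @param response_name Optional response label (`"rvsb"`, `"rvsg"`,
#'   `"absorbance"`).
#' @return An object of class `calibration_curve`: list with `analyte`,
#'   `response_name`, `concentrations`, `responses`, `slope`, `intercept`,
#'   `r_squared`, `degenerate`.
#' @examples
#' fit_calibration(c(1, 2, 3, 4), 0.01 * c(1, 2, 3, 4) + 0.2)
#' @export
fit_calibration <- function(concentrations, responses, analyte = NA_character_,
                            response_name = "response") {
  if (length(concentrations) != length(responses))
    stopf("`concentrations` and `responses` must have equal length")
  if (length(unique(concentrations)) < 3L)
    stopf("need at least 3 distinct concentrations to fit a calibration")
  if (any(!is.finite(concentrations)) || any(!is.finite(responses)))
    stopf("calibration data must be finite")
  fit <- lm(responses ~ concentrations)
  degenerate <- isTRUE(all.equal(sd(responses), 0))
  if (degenerate) {
    warning("responses have zero variance; r_squared set to 0", call. = FALSE)
    r2 <- 0
  } else {
    r2 <- cor(concentrations, responses)^2
  }
  structure(list(analyte = analyte, response_name = response_name,
                 concentrations = concentrations, responses = responses,
                 slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = r2, degenerate = degenerate),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration %s ~ concentration%s: slope %.5g, intercept %.5g, R^2 = %.4f%s\n",
              x$response_name,
              if (is.na(x$analyte)) "" else sprintf(" [%s]", x$analyte),
              x$slope, x$intercept, x$r_squared,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Percent API relative to an authentic reference tablet
#'
#' Because the colour responses are linear in concentration, content is
#' estimated as a direct proportional comparison with the authentic
#' reference: `percent = 100 * sample_response / reference_response`. For LF
#' the response is RvsB from the pre-acid image; for AM it is RvsG from the
#' post-acid image. Negative sample responses (pure noise around zero
#' concentration) are reported as 0%.
#'
#' @param sample_response Scalar response of the sample.
#' @param reference_response Scalar response of the authentic reference
#'   tablet; must be `> 0`.
#' @param analyte Optional label.
#' @return A list of class `api_estimate`: `analyte`, `percent_api`,
#'   `method = "reference-ratio"`.
#' @examples
#' percent_api(0.2, 0.4)$percent_api  # 50
#' @export
percent_api <- function(sample_response, reference_response,
                        analyte = NA_character_) {
  assert_scalar_num(sample_response, "sample_response")
  assert_scalar_num(reference_response, "reference_response")
  if (reference_response <= 0) stopf("`reference_response` must be > 0")
  structure(list(analyte = analyte,
                 percent_api = max(0, 100 * sample_response / reference_response),
                 method = "reference-ratio"),
            class = "api_estimate")
}

#' Tier III verdict from per-analyte content
#'
#' A sample passes when both analytes exceed their presence thresholds
#' (default 50% of the authentic reference); the absence of either active
#' ingredient designates a falsified product. No official numeric limit
#' exists for this assay, so the thresholds are configurable.
#'
#' @param lf_pct,am_pct Percent API for lumefantrine and artemether.
#' @param thresholds Named numeric `c(lf = , am = )` presence thresholds in
#'   percent.
#' @return A list: `verdict` (`"pass"`/`"fail"`), `lf_present`, `am_present`.
#' @examples
#' classify_colorimetric(111, 135)$verdict  # "pass"
#' classify_colorimetric(121, 0)$verdict    # "fail"
#' @export
classify_colorimetric <- function(lf_pct, am_pct, thresholds = c(lf = 50, am = 50)) {
  if (lf_pct < 0 || am_pct < 0) stopf("percent API values must be >= 0")
  lf_ok <- lf_pct > thresholds[["lf"]]
  am_ok <- am_pct > thresholds[["am"]]
  list(verdict = if (lf_ok && am_ok) "pass" else "fail",
       lf_present = lf_ok, am_present = am_ok)
}

#' Tier III quantification straight from plate images
#'
#' Runs the image -> channel-ratio -> percent-API pipeline for a set of
#' sample wells: LF is read as RvsB from the pre-acid image and AM as RvsG
#' from the post-acid image (the artemether product only develops after
#' sulfuric-acid treatment), each expressed relative to the authentic
#' reference tablet's wells.
#'
#' @param pre_image,post_image 8-bit RGB arrays of the plate before and
#'   after sulfuric-acid treatment (same layout).
#' @param layout A [plate_layout()].
#' @param wells A data frame with columns `sample_id`, `well`.
#' @param reference_id `sample_id` of the authentic reference tablet (must
#'   appear in `wells`).
#' @param thresholds Passed to [classify_colorimetric()].
#' @return A tibble per sample: `sample_id`, `rvsb`, `rvsg`, `lf_pct`,
#'   `am_pct`, `lf_present`, `am_present`, `verdict`.
#' @export
tier3_from_plates <- function(pre_image, post_image, layout, wells,
                              reference_id, thresholds = c(lf = 50, am = 50)) {
  if (!all(c("sample_id", "well") %in% names(wells)))
    stopf("`wells` needs columns `sample_id` and `well`")
  if (!reference_id %in% wells$sample_id)
    stopf("reference sample '%s' not found in `wells`", reference_id)
  pre <- do.call(rbind, lapply(wells$well, function(w) extract_well(pre_image, layout, w)))
  post <- do.call(rbind, lapply(wells$well, function(w) extract_well(post_image, layout, w)))
  rvsb <- pre$rvsb
  rvsg <- post$rvsg
  i_ref <- match(reference_id, wells$sample_id)
  out <- lapply(seq_len(nrow(wells)), function(i) {
    lf <- percent_api(rvsb[i], rvsb[i_ref], "LF")$percent_api
    am <- percent_api(rvsg[i], rvsg[i_ref], "AM")$percent_api
    cls <- classify_colorimetric(lf, am, thresholds)
    tibble::tibble(sample_id = wells$sample_id[i], rvsb = rvsb[i], rvsg = rvsg[i],
                   lf_pct = lf, am_pct = am,
                   lf_present = cls$lf_present, am_present = cls$am_present,
                   verdict = cls$verdict)
  })
  do.call(rbind, out)
}
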