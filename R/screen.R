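#' Screening-pipeline configuration
#'
#' @param gating `"always"` runs Tier III on every sample (as done for the
#'   six study counterfeits); `"on_fail"` reserves the destructive
#'   colorimetric tier for samples failing Tier I or Tier II, conserving
#'   reagents.
#' @param band_k Halfwidth multiplier for the fluorescence reference band.
#' @param presence_thresholds Named `c(lf = , am = )` percent thresholds for
#'   Tier III.
#' @param spec [spec_limits()] for Tier I.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(gating = c("always", "on_fail"), band_k = 3,
                          presence_thresholds = c(lf = 50, am = 50),
                          spec = spec_limits()) {
  gating <- match.arg(gating)
  structure(list(gating = gating, band_k = band_k,
                 presence_thresholds = presence_thresholds, spec = spec),
            class = "screen_config")
}

#' Run the integrated three-tier screen
#'
#' Executes Tier I (measurements vs specification), the two Tier II
#' photometric sub-tests (fluorescence band; laser W range) and Tier III
#' (colorimetric percent API) for every sample, and combines them into a
#' verdict table. A sample is `suspicious` as soon as any executed tier
#' fails — including the pattern where content is correct but photometrics
#' fail (a degraded/repackaged product is still not dispensable), so a Tier
#' III pass never overrides a Tier II failure. Tiers without data for a
#' sample are `skipped` with a reason. Every verdict carries its numeric
#' evidence in `reasons`.
#'
#' @param tablets Tier I data: data frame with `sample_id`, `weight_g`,
#'   `diameter_mm`, `thickness_mm`. Required for every sample.
#' @param cd3 Optional tibble `sample_id`, `intensity` (mean disc gray).
#' @param cd3_reference A [build_reference_band()], or a numeric vector of
#'   authentic intensities (band built with `config$band_k`).
#' @param codi Optional tibble `sample_id` plus either `w` or both
#'   `intensity_open` and `intensity_filtered`.
#' @param codi_reference A [codi_reference_range()], or a numeric vector of
#'   authentic W values.
#' @param tier3 Optional tibble `sample_id`, `lf_pct`, `am_pct` (e.g. from
#'   [tier3_from_plates()]).
#' @param config A [screen_config()].
#' @return A `screening_report`: tibble with columns `sample_id`, `tier1`,
#'   `tier2_cd3`, `tier2_codi`, `tier3` (each `"pass"`/`"fail"`/`"skipped"`),
#'   `overall` (`"clear"`/`"suspicious"`), `reasons`.
#' @export
run_screen <- function(tablets, cd3 = NULL, cd3_reference = NULL,
                       codi = NULL, codi_reference = NULL, tier3 = NULL,
                       config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  t1 <- screen_tablets(tablets, config$spec)
  ids <- t1$sample_id

  if (!is.null(cd3) && is.null(cd3_reference))
    stopf("`cd3_reference` is required when cd3 data are given")
  if (!is.null(cd3_reference) && !inherits(cd3_reference, "reference_band"))
    cd3_reference <- build_reference_band(cd3_reference, k = config$band_k)
  if (!is.null(codi) && is.null(codi_reference))
    stopf("`codi_reference` is required when codi data are given")
  if (!is.null(codi_reference) && !inherits(codi_reference, "reference_range"))
    codi_reference <- codi_reference_range(codi_reference)
  if (!is.null(codi) && !("w" %in% names(codi))) {
    if (!all(c("intensity_open", "intensity_filtered") %in% names(codi)))
      stopf("`codi` needs `w` or both `intensity_open` and `intensity_filtered`")
    codi$w <- compute_w(codi$intensity_open, codi$intensity_filtered)
  }

  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    reasons <- character()

    tier1 <- t1$verdict[i]
    bad <- c("weight", "diameter", "thickness")[!c(t1$weight_ok[i], t1$diameter_ok[i],
                                                   t1$thickness_ok[i])]
    reasons <- c(reasons, sprintf(
      "tier1 %s: %.3f g / %.2f mm / %.2f mm%s", tier1,
      tablets$weight_g[match(id, tablets$sample_id)],
      tablets$diameter_mm[match(id, tablets$sample_id)],
      tablets$thickness_mm[match(id, tablets$sample_id)],
      if (length(bad)) paste0(" (out of range: ", paste(bad, collapse = ", "), ")") else ""))

    if (is.null(cd3) || !id %in% cd3$sample_id) {
      tcd3 <- "skipped"
      reasons <- c(reasons, "tier2-cd3 skipped: no fluorescence reading")
    } else {
      inten <- cd3$intensity[match(id, cd3$sample_id)]
      v <- cd3_screen(inten, cd3_reference)
      tcd3 <- if (v == "pass") "pass" else "fail"
      reasons <- c(reasons, sprintf("tier2-cd3 %s: intensity %.1f vs band %.1f +/- %.1f",
                                    v, inten, cd3_reference$center, cd3_reference$halfwidth))
    }

    if (is.null(codi) || !id %in% codi$sample_id) {
      tcodi <- "skipped"
      reasons <- c(reasons, "tier2-codi skipped: no laser reading")
    } else {
      wv <- codi$w[match(id, codi$sample_id)]
      tcodi <- range_screen(wv, codi_reference)
      reasons <- c(reasons, sprintf("tier2-codi %s: W = %.2f vs range [%.2f, %.2f]",
                                    tcodi, wv, codi_reference$lo, codi_reference$hi))
    }

    gate_open <- config$gating == "always" ||
      tier1 == "fail" || tcd3 == "fail" || tcodi == "fail" ||
      tcd3 == "skipped" || tcodi == "skipped"
    if (!gate_open) {
      t3 <- "skipped"
      reasons <- c(reasons, "tier3 skipped: passed Tier I and both Tier II sub-tests")
    } else if (is.null(tier3) || !id %in% tier3$sample_id) {
      t3 <- "skipped"
      reasons <- c(reasons, "tier3 skipped: no colorimetric data")
    } else {
      j <- match(id, tier3$sample_id)
      cls <- classify_colorimetric(tier3$lf_pct[j], tier3$am_pct[j],
                                   config$presence_thresholds)
      t3 <- cls$verdict
      reasons <- c(reasons, sprintf("tier3 %s: LF %.0f%%, AM %.0f%% of reference",
                                    t3, tier3$lf_pct[j], tier3$am_pct[j]))
    }

    executed <- c(tier1, tcd3, tcodi, t3)
    overall <- if (any(executed == "fail")) "suspicious" else "clear"
    tibble::tibble(sample_id = id, tier1 = tier1, tier2_cd3 = tcd3,
                   tier2_codi = tcodi, tier3 = t3, overall = overall,
                   reasons = paste(reasons, collapse = " | "))
  })
  rep <- do.call(rbind, rows)
  class(rep) <- c("screening_report", class(rep))
  rep
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report: %d sample(s), %d suspicious\n",
              nrow(x), sum(x$overall == "suspicious")))
  NextMethod()
}

#' Write a screening report
#'
#' CSV or JSON with stable column/key order; [read_report()] round-trips
#' losslessly.
#'
#' @param report A `screening_report` from [run_screen()].
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  cols <- c("sample_id", "tier1", "tier2_cd3", "tier2_codi", "tier3",
            "overall", "reasons")
  d <- as.data.frame(report)[, cols, drop = FALSE]
  if (format == "csv") {
    write.csv(d, path, row.names = FALSE)
  } else {
    jsonlite::write_json(d, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a screening report written by [write_report()]
#'
#' @param path Path to a `.csv` or `.json` report.
#' @return A `screening_report` tibble.
#' @export
read_report <- function(path) {
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  d <- if (is_json) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    tryCatch(read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
             error = function(e) stopf("malformed report file '%s': %s", path,
                                       conditionMessage(e)))
  }
  cols <- c("sample_id", "tier1", "tier2_cd3", "tier2_codi", "tier3",
            "overall", "reasons")
  miss <- setdiff(cols, names(d))
  if (length(miss)) stopf("report '%s' is missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (nrow(d)) d[cols] <- lapply(d[cols], as.character)
  rep <- tibble::as_tibble(d[cols])
  class(rep) <- c("screening_report", class(rep))
  rep
}

#' Bundled six-sample counterfeit fixture
#'
#' Loads the packaged per-tier inputs for the six confirmed counterfeit
#' Coartem samples (CF1..CF6) plus the authentic references. Tier I inputs
#' are the published tablet measurements; the fluorescence intensities,
#' laser intensity pairs and colorimetric responses are synthetic stand-ins
#' (see the `_synthetic` files under `extdata/`), constructed to carry the
#' published per-tier outcomes, including the known W = 0.30 of CF6 and the
#' 121/111/135% content values.
#'
#' @return A list: `tablets`, `cd3`, `cd3_reference` (12 authentic
#'   intensities), `codi`, `codi_reference_w` (12 authentic W values),
#'   `tier3` (per-sample `lf_pct`/`am_pct` relative to the bundled
#'   reference response).
#' @export
load_counterfeit_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "tierscreen", mustWork = TRUE)
  tablets <- read_tablets(ext("tablets_table_measurements.csv"))
  cd3 <- tibble::as_tibble(read.csv(ext("cd3_intensities_synthetic.csv")))
  codi <- tibble::as_tibble(read.csv(ext("codi_readings_synthetic.csv")))
  resp <- tibble::as_tibble(read.csv(ext("tier3_responses_synthetic.csv")))

  cd3_ref <- cd3$intensity[cd3$group == "authentic"]
  cd3_s <- cd3[cd3$group != "authentic", c("sample_id", "intensity")]
  codi$w <- compute_w(codi$intensity_open, codi$intensity_filtered)
  codi_ref_w <- codi$w[codi$group == "authentic"]
  codi_s <- codi[codi$group != "authentic", c("sample_id", "w")]

  ref <- resp[resp$sample_id == "REF", ]
  smp <- resp[resp$sample_id != "REF", ]
  tier3 <- tibble::tibble(
    sample_id = smp$sample_id,
    lf_pct = vapply(smp$rvsb, function(x) percent_api(x, ref$rvsb)$percent_api, numeric(1)),
    am_pct = vapply(smp$rvsg, function(x) percent_api(x, ref$rvsg)$percent_api, numeric(1)))

  list(tablets = tablets, cd3 = cd3_s, cd3_reference = cd3_ref,
       codi = codi_s, codi_reference_w = codi_ref_w, tier3 = tier3)
}
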