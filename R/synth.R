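#' Synthetic-data generator configuration
#'
#' Bundles the seed and all generator models. Every generator is fully
#' deterministic given the seed; there is no hidden global random state.
#'
#' Model defaults (documented assumptions — the study reports no instrument
#' noise magnitudes):
#'
#' * `dimension_model`: per-profile mean/sd for weight (g), diameter (mm),
#'   thickness (mm). The authentic profile must keep each mean +/- 2 sd
#'   inside the specification range (validated); the counterfeit-dimension
#'   profile must be able to produce out-of-range tablets.
#' * `color_model`: the well colour is parameterised in ratio space so that
#'   `RvsB = rvsb_slope * c_LF` exactly (pre- and post-acid; the LF yellow
#'   is unchanged by acid) and `RvsG = rvsg_slope * c_AM` in the post-acid
#'   image only (the AM product develops on acid treatment). Channels are
#'   derived as `R` fixed and `B = R(1 - s c)/(1 + s c)` (analogously green),
#'   then quantised to 8 bits; the slopes are validated analytically to give
#'   strictly increasing, in-gamut responses over `[0, max_conc]`.
#' * `fluorescence_model`: per-class tablet-to-tablet intensity mean/sd and
#'   the dark background level for rendered fluorescence fields.
#' * `codi_model`: per-class log-normal medians/sdlogs for the unfiltered
#'   intensity `I` and for the filter ratio `rho = (1 - t)/t` where `t` is
#'   the filter transmission fraction; then `W = I * rho`, so the population
#'   median of W is exactly `intensity_median * wratio_median` (1.88 for the
#'   authentic defaults, anchored to the reported authentic median).
#'
#' @param seed Integer seed; required.
#' @param n_tablets Number of tablets for [generate_tablet_batch()].
#' @param tablet_profile One of `"authentic"`, `"counterfeit-dimension"`,
#'   `"counterfeit-content"`.
#' @param spec [spec_limits()] the dimension model is validated against.
#' @param dimension_model,color_model,fluorescence_model,codi_model Named
#'   lists overriding individual default entries (see Details).
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, n_tablets = 12)
#' @export
synth_config <- function(seed, n_tablets = 12,
                         tablet_profile = c("authentic", "counterfeit-dimension",
                                            "counterfeit-content"),
                         spec = spec_limits(),
                         dimension_model = list(), color_model = list(),
                         fluorescence_model = list(), codi_model = list()) {
  if (missing(seed)) stopf("`seed` is required: generators carry no global random state")
  assert_scalar_num(seed, "seed")
  if (n_tablets < 1) stopf("`n_tablets` must be >= 1")
  tablet_profile <- match.arg(tablet_profile)

  dim_def <- list(
    authentic = list(weight = c(mean = 0.240, sd = 0.003),
                     diameter = c(mean = 9.15, sd = 0.015),
                     thickness = c(mean = 3.2, sd = 0.05)),
    `counterfeit-dimension` = list(weight = c(mean = 0.300, sd = 0.020),
                                   diameter = c(mean = 9.6, sd = 0.30),
                                   thickness = c(mean = 3.6, sd = 0.15)),
    `counterfeit-content` = list(weight = c(mean = 0.240, sd = 0.003),
                                 diameter = c(mean = 9.15, sd = 0.015),
                                 thickness = c(mean = 3.2, sd = 0.05)))
  dm <- utils::modifyList(dim_def, dimension_model)

  cm <- utils::modifyList(list(
    red = 240, green_pre = 230,
    rvsb_slope = 0.5 / 36,   # RvsB per mg/mL LF: 0.5 at the 120% level (36 mg/mL)
    rvsg_slope = 0.5 / 6,    # RvsG per mg/mL AM: 0.5 at the 120% level (6 mg/mL)
    max_lf = 40, max_am = 7,
    background = c(210, 210, 210),
    pixel_sd = 4), color_model)

  fm <- utils::modifyList(list(
    authentic = c(mean = 150, sd = 5),
    `counterfeit-bright` = c(mean = 190, sd = 5),
    `counterfeit-dark` = c(mean = 110, sd = 5),
    background = 30, pixel_sd = 4), fluorescence_model)

  km <- utils::modifyList(list(
    authentic = list(family = "lognormal",
                     intensity_median = 2.0, intensity_sdlog = 0.15,
                     wratio_median = 0.94, wratio_sdlog = 0.25),
    counterfeit = list(family = "lognormal",
                       intensity_median = 2.0, intensity_sdlog = 0.15,
                       wratio_median = 0.20, wratio_sdlog = 0.30)), codi_model)

  cfg <- structure(list(seed = as.integer(seed), n_tablets = as.integer(n_tablets),
                        tablet_profile = tablet_profile, spec = spec,
                        dimension_model = dm, color_model = cm,
                        fluorescence_model = fm, codi_model = km),
                   class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @noRd
validate_synth_config <- function(cfg) {
  # authentic dimension regime: mean +/- 2 sd inside the spec range
  au <- cfg$dimension_model$authentic
  sp <- list(weight = cfg$spec$weight_g, diameter = cfg$spec$diameter_mm,
             thickness = cfg$spec$thickness_mm)
  for (nm in names(sp)) {
    p <- au[[nm]]
    if (any(p["sd"] < 0)) stopf("dimension sds must be >= 0")
    if (p["mean"] - 2 * p["sd"] < sp[[nm]][1] ||
        p["mean"] + 2 * p["sd"] > sp[[nm]][2])
      stopf("authentic %s model (mean %g, sd %g) does not keep +/-2 sd inside the spec range [%g, %g]",
            nm, p["mean"], p["sd"], sp[[nm]][1], sp[[nm]][2])
  }
  # counterfeit-dimension regime must be able to violate the spec
  cf <- cfg$dimension_model$`counterfeit-dimension`
  any_out <- mapply(function(p, iv) p[["sd"]] > 0 || p[["mean"]] < iv[1] || p[["mean"]] > iv[2],
                    cf, sp)
  if (!any(any_out))
    stopf("counterfeit-dimension model can never produce an out-of-range measurement")
  # colour model: analytic monotonicity + gamut check
  cm <- cfg$color_model
  if (cm$rvsb_slope <= 0 || cm$rvsg_slope <= 0)
    stopf("colour-model slopes must be > 0 (RvsB/RvsG strictly increasing in concentration)")
  if (cm$rvsb_slope * cm$max_lf >= 1 || cm$rvsg_slope * cm$max_am >= 1)
    stopf("colour-model slope * max concentration must be < 1 to stay in gamut")
  if (cm$red < 0 || cm$red > 255 || cm$green_pre < 0 || cm$green_pre > 255 ||
      any(cm$background < 0 | cm$background > 255))
    stopf("colour-model channel levels must lie in [0, 255]")
  if (cm$pixel_sd < 0) stopf("`pixel_sd` must be >= 0")
  # fluorescence model
  fm <- cfg$fluorescence_model
  for (cl in setdiff(names(fm), c("background", "pixel_sd")))
    if (fm[[cl]][["mean"]] < 0 || fm[[cl]][["mean"]] > 255 || fm[[cl]][["sd"]] < 0)
      stopf("fluorescence class '%s' must have mean in [0,255] and sd >= 0", cl)
  # codi model
  for (cl in names(cfg$codi_model)) {
    p <- cfg$codi_model[[cl]]
    if (p$intensity_median <= 0 || p$intensity_sdlog < 0 ||
        p$wratio_median < 0 || p$wratio_sdlog < 0)
      stopf("codi class '%s' needs intensity_median > 0, wratio_median >= 0, sdlogs >= 0", cl)
  }
  invisible(cfg)
}

#' Generate a batch of synthetic tablet measurements
#'
#' Draws weight, diameter and thickness from the profile's normal
#' distributions. The authentic profile is validated so its +/- 2 sd
#' intervals lie inside the specification ranges; the counterfeit-dimension
#' profile rejection-samples each tablet until at least one measurement
#' falls outside the specification (so every generated tablet fails Tier I);
#' the counterfeit-content profile has authentic-like dimensions (it passes
#' Tier I and must be caught downstream).
#'
#' @param config A [synth_config()].
#' @return A tibble of tablet records: `sample_id`, `weight_g`,
#'   `diameter_mm`, `thickness_mm`, `label`.
#' @examples
#' generate_tablet_batch(synth_config(seed = 1, n_tablets = 3))
#' @export
generate_tablet_batch <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  prof <- config$tablet_profile
  p <- config$dimension_model[[prof]]
  sp <- list(weight = config$spec$weight_g, diameter = config$spec$diameter_mm,
             thickness = config$spec$thickness_mm)
  withr::with_seed(config$seed, {
    draw1 <- function() vapply(p, function(q) rnorm(1, q[["mean"]], q[["sd"]]), numeric(1))
    rows <- lapply(seq_len(config$n_tablets), function(i) {
      m <- draw1()
      if (prof == "counterfeit-dimension") {
        tries <- 0L
        while (all(mapply(in_range, m, sp)) || any(m <= 0)) {
          m <- draw1(); tries <- tries + 1L
          if (tries > 1000L)
            stopf("counterfeit-dimension profile failed to violate the spec after 1000 draws")
        }
      } else {
        while (any(m <= 0)) m <- draw1()   # physical measurements are positive
      }
      m
    })
  })
  m <- do.call(rbind, rows)
  tibble::tibble(
    sample_id = sprintf("%s-%03d", switch(prof, authentic = "AUTH",
                                          `counterfeit-dimension` = "CFD",
                                          `counterfeit-content` = "CFC"),
                        seq_len(config$n_tablets)),
    weight_g = m[, "weight"], diameter_mm = m[, "diameter"],
    thickness_mm = m[, "thickness"],
    label = if (prof == "authentic") "authentic" else "counterfeit")
}

# Quantised 8-bit channel triple predicted by the colour model for a well.
#' @noRd
predict_channels <- function(lf, am, stage, color_model) {
  cm <- color_model
  ratio_channel <- function(base, s, conc) base * (1 - s * conc) / (1 + s * conc)
  r <- cm$red
  b <- ratio_channel(r, cm$rvsb_slope, lf)          # LF yellow: pre and post acid
  g <- if (stage == "pre-acid") cm$green_pre
       else ratio_channel(r, cm$rvsg_slope, am)     # AM product: post acid only
  round(clamp8(c(r, g, b)))
}

#' Model-predicted channel means for a well
#'
#' The exact (quantised) channel triple a zero-noise rendering produces, and
#' the RvsB/RvsG values it implies. Useful as ground truth when testing
#' extraction.
#'
#' @param lf,am Concentrations in mg/mL (`>= 0`).
#' @param stage `"pre-acid"` or `"post-acid"`.
#' @param config A [synth_config()].
#' @return A list: `channels` (named r/g/b), `rvsb`, `rvsg`.
#' @export
well_color_truth <- function(lf, am, stage = c("pre-acid", "post-acid"), config) {
  stage <- match.arg(stage)
  if (lf < 0 || am < 0) stopf("concentrations must be >= 0")
  ch <- predict_channels(lf, am, stage, config$color_model)
  list(channels = c(r = ch[1], g = ch[2], b = ch[3]),
       rvsb = (ch[1] - ch[3]) / (ch[1] + ch[3]),
       rvsg = (ch[1] - ch[2]) / (ch[1] + ch[2]))
}

#' Render a synthetic well-plate image
#'
#' Fills each listed well's circular ROI with the colour model's channel
#' values for its (LF, AM, stage) contents plus i.i.d. Gaussian pixel noise,
#' rounded and clamped to 8 bits, over a fixed neutral background. The image
#' dimensions come from the layout. Deterministic given `config$seed`.
#'
#' @param layout A [plate_layout()].
#' @param well_contents Data frame with columns `well`, `lf`, `am` (mg/mL)
#'   and `stage` (`"pre-acid"`/`"post-acid"`).
#' @param config A [synth_config()].
#' @return An 8-bit RGB array `c(height, width, 3)`.
#' @export
render_plate <- function(layout, well_contents, config) {
  stopifnot(inherits(config, "synth_config"))
  need <- c("well", "lf", "am", "stage")
  miss <- setdiff(need, names(well_contents))
  if (length(miss)) stopf("`well_contents` missing column(s): %s", paste(miss, collapse = ", "))
  if (any(well_contents$lf < 0 | well_contents$am < 0))
    stopf("concentrations must be >= 0")
  all_wells <- plate_wells(layout)
  bad <- setdiff(well_contents$well, all_wells)
  if (length(bad)) stopf("well(s) not in layout: %s", paste(bad, collapse = ", "))
  cm <- config$color_model
  img <- array(rep(cm$background, each = layout$height * layout$width),
               c(layout$height, layout$width, 3))
  withr::with_seed(config$seed, {
    for (i in seq_len(nrow(well_contents))) {
      wc <- well_contents[i, ]
      ch <- predict_channels(wc$lf, wc$am, wc$stage, cm)
      px <- disc_pixels(well_center(layout, wc$well), layout$roi_radius,
                        layout$width, layout$height)
      for (k in 1:3) {
        noise <- if (cm$pixel_sd > 0) rnorm(nrow(px), 0, cm$pixel_sd) else 0
        img[cbind(px$y + 1L, px$x + 1L, k)] <- round(clamp8(ch[k] + noise))
      }
    }
  })
  img
}

#' Render a synthetic tablet-fluorescence field
#'
#' Draws non-overlapping bright discs (tablets under UV illumination) on a
#' uniform dark background. The image is grayscale rendered as RGB: all
#' three channels share the same noisy value per pixel, so any valid gray
#' conversion recovers the disc intensity. The background must sit at least
#' 5 pixel-noise sds below the dimmest disc (validated), which is what
#' licenses threshold-based disc detection.
#'
#' @param positions Data frame with columns `x`, `y`, `radius` (pixels,
#'   0-based centres).
#' @param intensities Per-disc mean gray values in `[0, 255]`.
#' @param config A [synth_config()]; uses `fluorescence_model$background`
#'   and `$pixel_sd`.
#' @param width,height Image dimensions; defaults fit all discs with a
#'   margin.
#' @return An 8-bit RGB array.
#' @export
render_tablet_field <- function(positions, intensities, config,
                                width = NULL, height = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!all(c("x", "y", "radius") %in% names(positions)))
    stopf("`positions` needs columns x, y, radius")
  if (nrow(positions) != length(intensities))
    stopf("one intensity per disc required")
  if (any(intensities < 0 | intensities > 255))
    stopf("disc intensities must lie in [0, 255]")
  n <- nrow(positions)
  if (n > 1) {
    d <- as.matrix(stats::dist(positions[, c("x", "y")]))
    rr <- outer(positions$radius, positions$radius, `+`)
    diag(d) <- Inf
    if (any(d <= rr)) stopf("discs overlap")
  }
  fm <- config$fluorescence_model
  if (length(intensities) && fm$background >= min(intensities) - 5 * fm$pixel_sd)
    stopf("background (%g) must be < dimmest disc (%g) - 5 * pixel sd",
          fm$background, min(intensities))
  if (is.null(width)) width <- ceiling(max(positions$x + positions$radius, 0)) + 10
  if (is.null(height)) height <- ceiling(max(positions$y + positions$radius, 0)) + 10
  if (any(positions$x - positions$radius < 0 | positions$y - positions$radius < 0 |
          positions$x + positions$radius > width - 1 |
          positions$y + positions$radius > height - 1))
    stopf("discs must lie fully inside the %d x %d image", width, height)
  img <- array(fm$background, c(height, width, 3))
  withr::with_seed(config$seed, {
    for (i in seq_len(n)) {
      px <- disc_pixels(c(positions$x[i], positions$y[i]), positions$radius[i],
                        width, height)
      noise <- if (fm$pixel_sd > 0) rnorm(nrow(px), 0, fm$pixel_sd) else 0
      val <- round(clamp8(intensities[i] + noise))
      for (k in 1:3) img[cbind(px$y + 1L, px$x + 1L, k)] <- val
    }
  })
  img
}

#' Draw per-tablet fluorescence intensities
#'
#' Tablet-to-tablet intensity variation for a fluorescence class, before any
#' pixel noise: the class model of the rendered fields, usable directly when
#' only per-tablet intensities are needed.
#'
#' @param n Number of tablets.
#' @param class A class name of `config$fluorescence_model` (e.g.
#'   `"authentic"`, `"counterfeit-bright"`, `"counterfeit-dark"`).
#' @param config A [synth_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return Numeric vector of `n` intensities, clamped to `[0, 255]`.
#' @export
draw_cd3_intensities <- function(n, class, config, seed = config$seed) {
  fm <- config$fluorescence_model
  if (!class %in% names(fm)) stopf("unknown fluorescence class '%s'", class)
  p <- fm[[class]]
  withr::with_seed(seed, clamp8(rnorm(n, p[["mean"]], p[["sd"]])))
}

#' Simulate paired laser-transmission readings
#'
#' Draws the unfiltered intensity `I` and the filter transmission fraction
#' `t`, returns `(I, I_filter = t I)` pairs with the derived W. Under the
#' log-normal family (default) `W = I (1 - t)/t` is log-normal with
#' population median `intensity_median * wratio_median` (1.88 for the
#' authentic defaults). Under the `"normal"` family non-positive draws are
#' resampled, with an error after 100 consecutive rejections.
#'
#' @param n Number of tablets (`>= 0`).
#' @param class_params One entry of `config$codi_model`, or a class name
#'   when `config` is supplied.
#' @param seed Integer seed.
#' @param config Optional [synth_config()] used to resolve `class_params`
#'   by name.
#' @return A tibble: `sample_id`, `intensity_open`, `intensity_filtered`,
#'   `w`. Empty when `n = 0`.
#' @examples
#' simulate_codi(3, "authentic", seed = 1, config = synth_config(seed = 1))
#' @export
simulate_codi <- function(n, class_params, seed, config = NULL) {
  if (n < 0) stopf("`n` must be >= 0")
  if (is.character(class_params)) {
    if (is.null(config)) stopf("supply `config` to resolve class '%s'", class_params)
    nm <- class_params
    if (!nm %in% names(config$codi_model)) stopf("unknown codi class '%s'", nm)
    class_params <- config$codi_model[[nm]]
  }
  p <- class_params
  if (is.null(p$family)) p$family <- "lognormal"
  if (p$intensity_median <= 0) stopf("intensity distribution must be strictly positive")
  if (p$wratio_median < 0) stopf("`wratio_median` must be >= 0")
  empty <- tibble::tibble(sample_id = character(), intensity_open = numeric(),
                          intensity_filtered = numeric(), w = numeric())
  if (n == 0) return(empty)
  draw_pos <- function(ndraw, median_, sdlog_) {
    if (p$family == "lognormal") {
      rlnorm(ndraw, log(median_), sdlog_)
    } else {
      # normal family: resample non-positive draws, cap at 100 tries each
      x <- rnorm(ndraw, median_, sdlog_)
      tries <- 0L
      while (any(x <= 0)) {
        tries <- tries + 1L
        if (tries > 100L) stopf("resampling cap reached: distribution mass at <= 0 too large")
        bad <- x <= 0
        x[bad] <- rnorm(sum(bad), median_, sdlog_)
      }
      x
    }
  }
  withr::with_seed(seed, {
    I <- draw_pos(n, p$intensity_median, p$intensity_sdlog)
    rho <- if (p$wratio_median == 0 && p$wratio_sdlog == 0) rep(0, n)
           else draw_pos(n, p$wratio_median, p$wratio_sdlog)
  })
  t_frac <- 1 / (1 + rho)           # in (0, 1]
  If <- t_frac * I
  tibble::tibble(sample_id = sprintf("S-%04d", seq_len(n)),
                 intensity_open = I, intensity_filtered = If,
                 w = compute_w(I, If))
}

#' Write a complete synthetic dataset to disk
#'
#' Generates tablet measurements, a pre/post-acid plate image pair for a
#' small calibration series, a tablet-fluorescence field, and laser
#' readings, writing PNG images, CSV tables, and a JSON ground-truth
#' sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @return Invisibly, a named list of the written file paths.
#' @export
write_synthetic_dataset <- function(dir, config) {
  stopifnot(inherits(config, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)

  tablets <- generate_tablet_batch(config)
  write.csv(tablets, fp("tablets.csv"), row.names = FALSE)

  des <- design_dilution_series(dilution_design())
  lf <- des$concentration[des$analyte == "LF"]
  am <- des$concentration[des$analyte == "AM"]
  lay <- plate_layout(rows = 2, cols = 6, origin = c(14, 14), pitch = 20,
                      roi_radius = 7)
  wells <- tibble::tibble(well = plate_wells(lay)[seq_along(lf)], lf = lf, am = am)
  pre <- render_plate(lay, cbind(wells, stage = "pre-acid"), config)
  post <- render_plate(lay, cbind(wells, stage = "post-acid"), config)
  write_image_rgb(pre, fp("plate_pre_acid.png"))
  write_image_rgb(post, fp("plate_post_acid.png"))

  nf <- min(config$n_tablets, 8)
  pos <- tibble::tibble(x = 15 + 26 * (seq_len(nf) - 1) %% 4,
                        y = 15 + 26 * ((seq_len(nf) - 1) %/% 4), radius = 9)
  ints <- draw_cd3_intensities(nf, if (config$tablet_profile == "authentic")
    "authentic" else "counterfeit-bright", config)
  field <- render_tablet_field(pos, ints, config)
  write_image_rgb(field, fp("fluorescence_field.png"))

  codi <- simulate_codi(config$n_tablets,
                        if (config$tablet_profile == "authentic") "authentic" else "counterfeit",
                        seed = config$seed, config = config)
  write.csv(codi, fp("codi_readings.csv"), row.names = FALSE)

  truth <- list(seed = config$seed, tablet_profile = config$tablet_profile,
                dilution = list(lf_mg_ml = lf, am_mg_ml = am),
                plate_layout = list(rows = lay$rows, cols = lay$cols,
                                    origin = lay$origin, pitch = lay$pitch,
                                    roi_radius = lay$roi_radius),
                fluorescence = list(positions = pos, intensities = ints),
                codi_class = if (config$tablet_profile == "authentic") "authentic" else "counterfeit")
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(tablets = fp("tablets.csv"),
                 plate_pre = fp("plate_pre_acid.png"),
                 plate_post = fp("plate_post_acid.png"),
                 field = fp("fluorescence_field.png"),
                 codi = fp("codi_readings.csv"),
                 truth = fp("ground_truth.json")))
}
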