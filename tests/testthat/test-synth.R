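test_that("every generator is byte-identical under the same seed", {
  cfg <- synth_config(seed = 77, n_tablets = 10)
  expect_identical(generate_tablet_batch(cfg), generate_tablet_batch(cfg))

  lay <- plate_layout(rows = 1, cols = 2, origin = c(12, 12), pitch = 20,
                      roi_radius = 7)
  wc <- tibble::tibble(well = c("A1", "A2"), lf = c(30, 15), am = c(5, 2.5),
                       stage = "pre-acid")
  expect_identical(render_plate(lay, wc, cfg), render_plate(lay, wc, cfg))

  pos <- tibble::tibble(x = c(15, 40), y = 15, radius = 8)
  expect_identical(render_tablet_field(pos, c(150, 180), cfg),
                   render_tablet_field(pos, c(150, 180), cfg))

  expect_identical(simulate_codi(20, "authentic", seed = 77, config = cfg),
                   simulate_codi(20, "authentic", seed = 77, config = cfg))
})

test_that("authentic batches with degenerate noise always pass Tier I", {
  cfg <- synth_config(seed = 2, n_tablets = 25,
                      dimension_model = list(authentic = list(
                        weight = c(mean = 0.240, sd = 0),
                        diameter = c(mean = 9.15, sd = 0),
                        thickness = c(mean = 3.2, sd = 0))))
  res <- screen_tablets(generate_tablet_batch(cfg))
  expect_true(all(res$verdict == "pass"))
})

test_that("counterfeit-dimension batches always fail Tier I", {
  cfg <- synth_config(seed = 83, n_tablets = 50,
                      tablet_profile = "counterfeit-dimension")
  res <- screen_tablets(generate_tablet_batch(cfg))
  expect_equal(sum(res$verdict == "fail"), 50)
})

test_that("dimension regimes that cannot meet their contract are rejected", {
  # authentic mean outside the spec range
  expect_error(synth_config(seed = 1, dimension_model = list(authentic = list(
    weight = c(mean = 0.300, sd = 0.003),
    diameter = c(mean = 9.15, sd = 0.02),
    thickness = c(mean = 3.2, sd = 0.05)))), "spec range")
  # counterfeit-dimension model that can never violate the spec
  expect_error(synth_config(seed = 1, dimension_model = list(
    `counterfeit-dimension` = list(weight = c(mean = 0.240, sd = 0),
                                   diameter = c(mean = 9.15, sd = 0),
                                   thickness = c(mean = 3.2, sd = 0)))),
    "never produce")
})

test_that("the colour model is validated analytically and renders monotone ratios", {
  expect_error(synth_config(seed = 1, color_model = list(rvsb_slope = -0.01)),
               "strictly increasing")
  expect_error(synth_config(seed = 1, color_model = list(rvsb_slope = 0.03, max_lf = 40)),
               "gamut")

  cfg <- synth_config(seed = 5, color_model = list(pixel_sd = 0))
  lay <- plate_layout(rows = 1, cols = 2, origin = c(12, 12), pitch = 20,
                      roi_radius = 7)
  wc <- tibble::tibble(well = c("A1", "A2"), lf = c(15, 30), am = 0,
                       stage = "pre-acid")
  img <- render_plate(lay, wc, cfg)
  m <- measure_plate(img, lay, wells = c("A1", "A2"))
  expect_gt(m$rvsb[2], m$rvsb[1])   # RvsB increasing in LF concentration
  # zero-noise ROI means equal the quantised model prediction exactly
  truth <- well_color_truth(30, 0, "pre-acid", cfg)
  expect_equal(unname(c(m$mean_red[2], m$mean_green[2], m$mean_blue[2])),
               unname(truth$channels))
  expect_error(render_plate(lay, tibble::tibble(well = "A1", lf = -1, am = 0,
                                                stage = "pre-acid"), cfg), ">= 0")
  expect_error(render_plate(lay, tibble::tibble(well = "C9", lf = 1, am = 0,
                                                stage = "pre-acid"), cfg), "not in layout")
})

test_that("rendered fields have valid 8-bit pixels, exact zero-noise discs, no overlap", {
  cfg0 <- synth_config(seed = 7, fluorescence_model = list(pixel_sd = 0))
  pos <- tibble::tibble(x = 20, y = 20, radius = 9)
  img <- render_tablet_field(pos, 180, cfg0, width = 41, height = 41)
  expect_equal(disc_mean_gray(img, c(20, 20), 9), 180)

  cfg <- synth_config(seed = 7)
  pos2 <- tibble::tibble(x = c(16, 44), y = 16, radius = c(9, 9))
  img2 <- render_tablet_field(pos2, c(200, 120), cfg)
  expect_true(all(img2 >= 0 & img2 <= 255 & img2 == round(img2)))
  m <- vapply(1:2, function(i) disc_mean_gray(img2, c(pos2$x[i], pos2$y[i]), 7),
              numeric(1))
  expect_gt(m[1], m[2])

  overlap <- tibble::tibble(x = c(20, 30), y = 20, radius = c(9, 9))
  expect_error(render_tablet_field(overlap, c(150, 150), cfg), "overlap")
  expect_error(render_tablet_field(pos, 300, cfg), "\\[0, 255\\]")
  # background must sit well below the dimmest disc
  expect_error(render_tablet_field(pos, 40, cfg), "background")
})

test_that("simulated laser readings honour their distributional contracts", {
  cfg <- synth_config(seed = 89)
  # transmission fraction == 1 (ratio 0) means the filter removes nothing
  all_pass <- simulate_codi(15, list(intensity_median = 2, intensity_sdlog = 0.1,
                                     wratio_median = 0, wratio_sdlog = 0), seed = 3)
  expect_true(all(all_pass$w == 0))
  expect_equal(nrow(simulate_codi(0, "authentic", seed = 1, config = cfg)), 0)

  big <- simulate_codi(10000, "authentic", seed = 91, config = cfg)
  expect_true(all(big$intensity_open > 0 & big$intensity_filtered > 0))
  expect_true(all(big$intensity_filtered <= big$intensity_open))  # t in (0, 1]
  # sample median within 5% of the configured population median (1.88)
  expect_lt(abs(median(big$w) - 1.88) / 1.88, 0.05)

  # normal family: non-positive draws are resampled away
  nrm <- simulate_codi(200, list(family = "normal", intensity_median = 2,
                                 intensity_sdlog = 1.5, wratio_median = 1,
                                 wratio_sdlog = 0.8), seed = 5)
  expect_true(all(nrm$intensity_open > 0 & nrm$intensity_filtered > 0))
  expect_error(simulate_codi(5, list(intensity_median = -1, intensity_sdlog = 0.1,
                                     wratio_median = 1, wratio_sdlog = 0.1), seed = 5),
               "strictly positive")
})

test_that("a written synthetic dataset round-trips from disk", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 97, n_tablets = 6)
  paths <- write_synthetic_dataset(dir, cfg)
  expect_true(all(file.exists(unlist(paths))))
  tab <- read_tablets(paths$tablets)
  expect_equal(nrow(tab), 6)
  img <- read_image_rgb(paths$plate_pre)
  expect_equal(dim(img)[3], 3)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$seed, 97)
  expect_equal(truth$dilution$lf_mg_ml, c(36, 30, 24, 15, 7.5, 3))
  # the written plate image reproduces the in-memory rendering
  des <- design_dilution_series(dilution_design())
  lay <- plate_layout(rows = 2, cols = 6, origin = c(14, 14), pitch = 20,
                      roi_radius = 7)
  wells <- tibble::tibble(well = plate_wells(lay)[1:6],
                          lf = des$concentration[des$analyte == "LF"],
                          am = des$concentration[des$analyte == "AM"],
                          stage = "pre-acid")
  expect_identical(img, render_plate(lay, wells, cfg))
})
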