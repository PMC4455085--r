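uniform_plate <- function(rgb, lay) {
  img <- array(0, c(lay$height, lay$width, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}

test_that("channel ratios from a uniform well are exact", {
  lay <- plate_layout(rows = 1, cols = 1, origin = c(10, 10), pitch = 21,
                      roi_radius = 6)
  m <- extract_well(uniform_plate(c(200, 150, 100), lay), lay, "A1")
  expect_equal(m$rvsb, 100 / 300)
  expect_equal(m$rvsg, 50 / 350)
  # achromatic wells have both ratios exactly zero
  m0 <- extract_well(uniform_plate(c(77, 77, 77), lay), lay, "A1")
  expect_equal(m0$rvsb, 0)
  expect_equal(m0$rvsg, 0)
})

test_that("extract_well matches a brute-force per-pixel loop exactly", {
  cfg <- synth_config(seed = 5)
  lay <- plate_layout(rows = 2, cols = 3, origin = c(13, 13), pitch = 20,
                      roi_radius = 7)
  wc <- tibble::tibble(well = c("A1", "B3"), lf = c(30, 15), am = c(5, 0),
                       stage = "pre-acid")
  img <- render_plate(lay, wc, cfg)
  for (w in c("A1", "B3")) {
    got <- extract_well(img, lay, w)
    ctr <- well_center(lay, w)
    sums <- c(0, 0, 0); np <- 0
    for (y in 0:(lay$height - 1)) for (x in 0:(lay$width - 1)) {
      if ((x - ctr[1])^2 + (y - ctr[2])^2 <= lay$roi_radius^2) {
        np <- np + 1
        sums <- sums + img[y + 1, x + 1, ]
      }
    }
    expect_equal(got$n_pixels, np)
    expect_equal(c(got$mean_red, got$mean_green, got$mean_blue), sums / np)
  }
})

test_that("ratios stay in [-1, 1] and are invariant to uniform channel rescaling", {
  set.seed(91)
  lay <- plate_layout(rows = 1, cols = 1, origin = c(8, 8), pitch = 17,
                      roi_radius = 5)
  for (i in 1:50) {
    ch <- runif(3, 30, 120)
    k <- runif(1, 1, 2)
    r1 <- (ch[1] - ch[3]) / (ch[1] + ch[3])
    m <- extract_well(uniform_plate(round(ch), lay), lay, "A1")
    expect_true(m$rvsb >= -1 && m$rvsb <= 1)
    expect_true(m$rvsg >= -1 && m$rvsg <= 1)
    # exact in real arithmetic; 8-bit quantisation perturbs by < 1/min-sum
    m2 <- extract_well(uniform_plate(round(ch * k), lay), lay, "A1")
    expect_lt(abs(m$rvsb - r1), 0.02)
    expect_lt(abs(m2$rvsb - r1), 0.02)
  }
})

test_that("ROI means of noisy wells stay within the standard-error bound", {
  # pixel noise sd 4 over a ~200-pixel ROI: mean within 3 * 4 / sqrt(n)
  cfg <- synth_config(seed = 17, color_model = list(pixel_sd = 4))
  lay <- plate_layout(rows = 1, cols = 2, origin = c(12, 12), pitch = 24,
                      roi_radius = 8)
  wc <- tibble::tibble(well = c("A1", "A2"), lf = c(30, 7.5), am = 0,
                       stage = "pre-acid")
  img <- render_plate(lay, wc, cfg)
  for (i in 1:2) {
    m <- extract_well(img, lay, wc$well[i])
    expect_gte(m$n_pixels, 190)
    truth <- well_color_truth(wc$lf[i], 0, "pre-acid", cfg)
    bound <- 3 * 4 / sqrt(m$n_pixels) + 0.5  # + rounding half-step
    expect_lt(abs(m$mean_red - truth$channels[["r"]]), bound)
    expect_lt(abs(m$mean_blue - truth$channels[["b"]]), bound)
    expect_lt(abs(m$rvsb - truth$rvsb), 0.02)
  }
})

test_that("gray conversion is a weighted channel mean", {
  expect_equal(gray_value(120, 120, 120, c(0.2, 0.5, 0.3)), 120)
  expect_equal(gray_value(90, 180, 0), 90)
  expect_error(gray_value(1, 2, 3, c(0.5, 0.5, 0.5)), "summing to 1")
  # default-weight disc conversion matches an independent per-pixel loop
  cfg <- synth_config(seed = 23)
  pos <- tibble::tibble(x = 20, y = 20, radius = 9)
  img <- render_tablet_field(pos, 180, cfg, width = 41, height = 41)
  got <- disc_mean_gray(img, c(20, 20), 9)
  acc <- 0; np <- 0
  for (y in 0:40) for (x in 0:40) if ((x - 20)^2 + (y - 20)^2 <= 81) {
    np <- np + 1
    acc <- acc + mean(img[y + 1, x + 1, ])
  }
  expect_equal(got, acc / np)
})

test_that("disc detection recovers the rendered field geometry", {
  cfg <- synth_config(seed = 41)
  pos <- tibble::tibble(x = rep(c(16, 42, 68, 94), 2),
                        y = rep(c(16, 42), each = 4), radius = 9)
  ints <- c(200, 120, 180, 150, 160, 210, 140, 130)
  img <- render_tablet_field(pos, ints, cfg)
  rois <- tablet_rois(img, expected_discs = 8)
  expect_equal(nrow(rois), 8)
  # row-major order matches the construction; centres within 1 px
  expect_true(all(abs(rois$x - pos$x) <= 1))
  expect_true(all(abs(rois$y - pos$y) <= 1))
  # extracted means preserve the intensity ordering of bright vs dim discs
  means <- vapply(1:8, function(i)
    disc_mean_gray(img, c(rois$x[i], rois$y[i]), rois$radius[i] * 0.8), numeric(1))
  expect_gt(means[1], means[2])   # 200-disc brighter than 120-disc
  expect_equal(order(means), order(ints))

  blank <- array(30, c(40, 40, 3))
  expect_equal(nrow(tablet_rois(blank, expected_discs = 0)), 0)
  expect_error(tablet_rois(blank, expected_discs = 6), "expected 6")
})

test_that("diameter profiles have plateau at disc intensity and flanks at background", {
  cfg0 <- synth_config(seed = 3, fluorescence_model = list(pixel_sd = 0))
  pos <- tibble::tibble(x = 25, y = 25, radius = 10)
  img <- render_tablet_field(pos, 180, cfg0, width = 51, height = 51)
  pr <- diameter_profile(img, c(25, 25), 10, margin = 5)
  expect_length(pr$positions, 2 * (10 + 5) + 1)
  expect_length(pr$gray_values, length(pr$positions))
  inside <- abs(pr$positions) <= 10
  expect_true(all(pr$gray_values[inside] == 180))
  expect_true(all(pr$gray_values[!inside] == 30))
  expect_equal(pr$summary, 180)
  expect_error(diameter_profile(img, c(25, 25), 30), "outside the image")

  # noisy disc: plateau mean within 3 sd / sqrt(n) of the true level
  cfg <- synth_config(seed = 29, fluorescence_model = list(pixel_sd = 4))
  imgn <- render_tablet_field(pos, 180, cfg, width = 51, height = 51)
  prn <- diameter_profile(imgn, c(25, 25), 10, margin = 5)
  plateau <- prn$gray_values[abs(prn$positions) <= 10]
  expect_lt(abs(mean(plateau) - 180), 3 * 4 / sqrt(length(plateau)) + 0.5)
})
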