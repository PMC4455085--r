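# Shared simulation helpers used by module tests and the acceptance suite.

# Zero-noise plate pipeline: render wells at the given %-of-reference levels,
# extract RvsB/RvsG, and return estimated percent API per level.
zero_noise_recovery <- function(levels_pct = c(10, 25, 50, 80, 100, 120),
                                seed = 11) {
  cfg <- synth_config(seed = seed, color_model = list(pixel_sd = 0))
  n <- length(levels_pct) + 1
  lay <- plate_layout(rows = 1, cols = n, origin = c(12, 12), pitch = 20,
                      roi_radius = 7)
  wc <- tibble::tibble(well = paste0("A", seq_len(n)),
                       lf = c(levels_pct, 100) * 0.30,   # 100% = 30 mg/mL LF
                       am = c(levels_pct, 100) * 0.05,   # 100% = 5 mg/mL AM
                       stage = "pre-acid")
  pre <- render_plate(lay, wc, cfg)
  wc$stage <- "post-acid"
  post <- render_plate(lay, wc, cfg)
  wells <- tibble::tibble(sample_id = c(paste0("L", levels_pct), "REF"),
                          well = paste0("A", seq_len(n)))
  t3 <- tier3_from_plates(pre, post, lay, wells, "REF")
  t3 <- t3[t3$sample_id != "REF", ]
  t3$true_pct <- levels_pct
  t3
}

# Full end-to-end batch: n_auth authentic + n_cf counterfeit samples through
# all tiers, with reference assets built from a 100-tablet authentic panel
# (the min-max W range has an intrinsic 2/(n+1) false-alarm rate, so small
# reference panels dominate the error budget).
run_end_to_end <- function(seed, n_auth = 20, n_cf = 20, n_ref = 100,
                           gating = "always") {
  cfg <- synth_config(seed = seed)

  # --- samples: tier 1 measurements
  auth <- generate_tablet_batch(synth_config(seed = seed, n_tablets = n_auth,
                                             tablet_profile = "authentic"))
  n_dim <- n_cf %/% 2
  cfd <- generate_tablet_batch(synth_config(seed = seed + 1, n_tablets = n_dim,
                                            tablet_profile = "counterfeit-dimension"))
  cfc <- generate_tablet_batch(synth_config(seed = seed + 2,
                                            n_tablets = n_cf - n_dim,
                                            tablet_profile = "counterfeit-content"))
  tablets <- rbind(auth, cfd, cfc)
  truth <- tablets$label

  # --- tier 2 CD-3: one rendered field per batch, discs detected and measured
  n <- nrow(tablets)
  per_row <- 8
  pos <- tibble::tibble(x = 15 + 26 * ((seq_len(n) - 1) %% per_row),
                        y = 15 + 26 * ((seq_len(n) - 1) %/% per_row),
                        radius = 8)
  classes <- ifelse(truth == "authentic", "authentic",
                    rep(c("counterfeit-bright", "counterfeit-dark"), length.out = n))
  classes[truth == "authentic"] <- "authentic"
  ints <- numeric(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    ints[idx] <- draw_cd3_intensities(length(idx), cl, cfg, seed = seed + 3)[seq_along(idx)]
  }
  field <- render_tablet_field(pos, ints, cfg)
  rois <- tablet_rois(field, expected_discs = n)
  cd3 <- tibble::tibble(
    sample_id = tablets$sample_id,   # row-major detection matches layout order
    intensity = vapply(seq_len(n), function(i)
      disc_mean_gray(field, c(rois$x[i], rois$y[i]), rois$radius[i] * 0.8),
      numeric(1)))
  cd3_ref <- draw_cd3_intensities(n_ref, "authentic", cfg, seed = seed + 4)

  # --- tier 2 CoDI
  codi_auth <- simulate_codi(n_auth, "authentic", seed = seed + 5, config = cfg)
  codi_cf <- simulate_codi(n_cf, "counterfeit", seed = seed + 6, config = cfg)
  codi <- rbind(codi_auth, codi_cf)
  codi$sample_id <- tablets$sample_id
  codi_ref <- simulate_codi(n_ref, "authentic", seed = seed + 7, config = cfg)$w

  # --- tier 3: plates (pre/post acid) with one well per sample + reference
  lay <- plate_layout(rows = 8, cols = 6, origin = c(12, 12), pitch = 18,
                      roi_radius = 6)
  wells <- tibble::tibble(sample_id = c(tablets$sample_id, "REF"),
                          well = plate_wells(lay)[seq_len(n + 1)])
  conc <- tibble::tibble(
    well = wells$well,
    lf = c(ifelse(truth == "authentic", 30, 0), 30),
    am = c(ifelse(truth == "authentic", 5, 0), 5),
    stage = "pre-acid")
  pre <- render_plate(lay, conc, synth_config(seed = seed + 8))
  conc$stage <- "post-acid"
  post <- render_plate(lay, conc, synth_config(seed = seed + 9))
  t3 <- tier3_from_plates(pre, post, lay, wells, "REF")
  t3 <- t3[t3$sample_id != "REF", ]

  rep <- run_screen(tablets, cd3 = cd3, cd3_reference = cd3_ref,
                    codi = codi[c("sample_id", "w")], codi_reference = codi_ref,
                    tier3 = t3[c("sample_id", "lf_pct", "am_pct")],
                    config = screen_config(gating = gating))
  expected <- ifelse(truth == "authentic", "clear", "suspicious")
  list(report = rep, truth = truth,
       accuracy = mean(rep$overall == expected))
}

# Brute-force Mann-Whitney oracle: enumerate every size-na subset of the
# pooled observations, recompute U by direct pair counting, and take the
# doubled smaller tail.
mw_brute_force <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U_obs <- u_of(a, b)
  idx <- combn(length(pool), na)
  Us <- apply(idx, 2, function(s) u_of(pool[s], pool[-s]))
  eps <- 1e-9
  p_le <- mean(Us <= U_obs + eps)
  p_ge <- mean(Us >= U_obs - eps)
  list(U = U_obs, p = min(1, 2 * min(p_le, p_ge)))
}
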