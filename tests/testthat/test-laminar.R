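test_that("depth profile recovers the laminar power and phase structure", {
  g <- fix_session("ferret", duration_s = 120)
  prof <- theta_depth_profile(g$session, min_locomotion_s = 20)
  expect_equal(prof$phase_shift_deg[1], 0)          # top channel by definition
  # total shift across the cell layer ~180 degrees
  total <- thetaquant:::wrap180(prof$phase_shift_deg[8] -
                                prof$phase_shift_deg[1])
  expect_lt(abs(abs(total) - 180), 15)
  # shift is monotone in depth through the layer
  ph <- cumsum(c(0, abs(thetaquant:::wrap180(diff(prof$phase_shift_deg)))))
  expect_true(all(diff(ph) >= -5))
  # power profile tracks the generator amplitude profile (rank order)
  expect_gt(cor(sqrt(prof$power_median), g$truth$amp_profile,
                method = "spearman"), 0.9)
})

test_that("uniform amplitude profile yields a flat power profile", {
  cfg <- generator_config("ferret", duration_s = 90, n_channels = 6,
                          sp_channel = 4, seed = 17,
                          theta_amp_profile = rep(100, 6),
                          phase_shift_profile = rep(0, 6))
  g <- generate_session(cfg, artifacts = FALSE)
  prof <- theta_depth_profile(g$session, min_locomotion_s = 15)
  rel <- prof$power_median / max(prof$power_median)
  expect_lt(max(rel) - min(rel), 0.1)
})

test_that("insufficient locomotion raises an error", {
  g <- fix_session("ferret", duration_s = 120)
  s <- g$session
  s$speed <- rep(1, length(s$speed))
  expect_error(theta_depth_profile(s), "locomotion")
})

test_that("speed-frequency slope is recovered and null slopes are not flagged", {
  prof <- species_profile("ferret")
  fs <- 1000
  # recovery condition: theta always on, frequency coupled to speed only
  slopes <- sapply(1:3, function(seed) {
    cfg <- generator_config("ferret", duration_s = 150, n_channels = 8,
                            sp_channel = 4, speed_freq_slope = 0.03,
                            immobility_freq_offset = 0, seed = 100 + seed)
    g <- generate_session(cfg, artifacts = FALSE)
    x <- g$session$recording$samples[8, ]
    inst <- instantaneous_theta(
      detect_extrema(bandpass_theta(x, prof, fs)), length(x), fs)
    speed_theta_regression(inst, g$session$speed, fs, "frequency",
                           prof)$beta1
  })
  expect_lt(abs(mean(slopes) - 0.03), 0.005)
  # speed-independent frequency: CI covers zero, no significance
  set.seed(5)
  n <- 120 * fs
  inst0 <- data.frame(frequency = 7.5 + rnorm(n, 0, 0.3),
                      amplitude = 1, power = 1, phase = 0)
  v <- pmax(0, 20 + 10 * sin(2 * pi * (1:n) / n * 6) + rnorm(n))
  r0 <- speed_theta_regression(inst0, v, fs, "frequency", prof)
  expect_gt(r0$p, bonferroni_alpha(32))
  # negative power coupling is detected with the right sign
  instn <- data.frame(frequency = 7.5,
                      amplitude = 1, phase = 0,
                      power = 4000 - 50 * v + rnorm(n, 0, 100))
  rn <- speed_theta_regression(instn, v, fs, "power", prof)
  expect_lt(rn$beta1, 0)
  expect_lt(rn$p, bonferroni_alpha(32))
})

test_that("regression refuses degenerate bin structure", {
  prof <- species_profile("rat")
  inst <- data.frame(frequency = rep(8, 3000), amplitude = 1, power = 1,
                     phase = 0)
  expect_warning(r <- speed_theta_regression(inst, rep(12, 3000), 1000,
                                             "frequency", prof),
                 "bins|epochs")
  expect_null(r)
})

test_that("layer assignment follows the dip-plus-shift rule with fallback", {
  # constructed profile: SP at channel 15, 100 um spacing
  prof <- data.frame(channel = 1:32, depth_um = (0:31) * 100,
                     power_median = c(rep(100, 12), 130, 70, 25, 90,
                                      rep(140, 16)),
                     phase_shift_deg = c(rep(0, 13), 30, 90, 150,
                                         rep(180, 16)))
  lay <- estimate_layers(prof)
  expect_equal(lay$sp, 15)
  expect_equal(lay$so, 13)
  expect_equal(lay$srslm, 19)
  expect_equal(lay$method, "profile")
  # monotone power, no phase shift: fallback to the power peak
  prof2 <- data.frame(channel = 1:10, depth_um = (0:9) * 100,
                      power_median = seq(10, 100, by = 10),
                      phase_shift_deg = 0)
  expect_warning(lay2 <- estimate_layers(prof2), "flat|power")
  expect_equal(lay2$method, "power-peak fallback")
  expect_equal(lay2$so, 10)
  expect_true(is.na(lay2$srslm))
})

test_that("layer recovery works end to end on synthetic probes", {
  hits <- 0
  for (sp_ch in c(9, 20)) {
    cfg <- generator_config("ferret", duration_s = 240, n_channels = 32,
                            sp_channel = sp_ch, seed = 300 + sp_ch,
                            trial_spec = list(run_plateau_dur = c(2.5, 3.5),
                                              reward_dwell_s = 1.0))
    g <- generate_session(cfg, artifacts = FALSE)
    prof <- theta_depth_profile(g$session, regressions = FALSE)
    lay <- estimate_layers(prof)
    expect_lte(abs(lay$sp - sp_ch), 1)
    if (lay$sp == sp_ch) hits <- hits + 1
  }
  expect_gte(hits, 1)
})

test_that("ripple power localises an injected burst at the cell layer", {
  fs <- 1000
  set.seed(23)
  n <- 20 * fs
  samples <- matrix(rnorm(8 * n, sd = 20), 8, n)
  burst_t <- rep(seq(2, 18, by = 2) * fs, each = 80) +
    rep(1:80, times = 9)
  samples[5, burst_t] <- samples[5, burst_t] +
    60 * sin(2 * pi * 200 * (1:length(burst_t)) / fs)
  rec <- new_recording(samples, fs, (0:7) * 100)
  rp <- ripple_power_profile(rec)
  expect_equal(which.max(rp$rms), 5)
  # near-flat profile without ripple content
  rec0 <- new_recording(matrix(rnorm(8 * n, sd = 20), 8, n), fs, (0:7) * 100)
  rp0 <- ripple_power_profile(rec0)
  expect_lt(diff(range(rp0$rms)) / mean(rp0$rms), 0.1)
  expect_error(ripple_power_profile(rec, band = c(250, 150)), "lo >= hi")
  expect_error(ripple_power_profile(
    new_recording(matrix(0, 2, 100), 300, c(0, 100))), "too low")
})
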