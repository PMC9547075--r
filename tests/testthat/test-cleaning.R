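fs <- 1000

test_that("Welch PSD resolves tones, noise floors and theta harmonics", {
  t20 <- (0:(20 * fs - 1)) / fs
  psd <- compute_psd(sin(2 * pi * 6 * t20), fs)
  expect_lt(abs(psd$freq[which.max(psd$power_db)] - 6), fs / 4096)
  # white noise: flat within Welch estimator variance (~1/sqrt(K) in
  # linear power, generous dB bound over the averaged spectrum)
  set.seed(1)
  psdw <- compute_psd(rnorm(60 * fs), fs)
  sel <- psdw$freq > 10 & psdw$freq < 400
  expect_lt(diff(range(psdw$power_db[sel])), 6)
  # sawtooth-skewed theta carries a harmonic at 2f
  g <- fix_session("rat", duration_s = 120)
  x <- g$session$recording$samples[8, ]
  run <- rle(g$truth$state == "moving")
  ends <- cumsum(run$lengths)
  i <- which(run$values)[which.max(run$lengths[run$values])]
  idx <- (ends[i] - run$lengths[i] + 1):ends[i]
  psdm <- compute_psd(x[idx], fs, nfft = 2048)
  f0 <- mean(g$truth$freq[idx])
  at <- function(f) max(psdm$power_db[abs(psdm$freq - f) < 0.7])
  flank <- function(f) median(psdm$power_db[abs(psdm$freq - f) > 1.5 &
                                            abs(psdm$freq - f) < 3])
  expect_gt(at(2 * f0) - flank(2 * f0), 6)   # harmonic peak present
  expect_error(compute_psd(rep(NA_real_, 5000), fs),
               "masked|valid")
})

test_that("channel selection excludes silent-theta and mains-dominated channels", {
  set.seed(3)
  n <- 40 * fs
  tt <- (0:(n - 1)) / fs
  lia <- function() thetaquant:::lia_noise(n, fs, 1.5, 30)
  good <- 80 * sin(2 * pi * 6 * tt) + lia()
  silent <- lia()
  mains <- 80 * sin(2 * pi * 6 * tt) + 800 * sin(2 * pi * 50 * tt) + lia()
  rec <- new_recording(rbind(good, silent, mains, good), fs,
                       c(0, 100, 200, 300))
  sel <- select_channels(rec, species_profile("rat"))
  expect_equal(sel$include, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sel$reasons, c("ok", "low_theta", "mains", "ok"))
  expect_false(sel$all_excluded)
})

test_that("amplitude artifact detection: clean data untouched, transients masked", {
  g <- fix_session("rat", duration_s = 120)           # artifact-free
  det <- detect_amplitude_artifacts(g$session$recording)
  expect_lt(mean(det$mask), 0.005)
  # inject a 20x transient and a 500 ms zero dropout
  rec <- g$session$recording
  typical <- median(abs(rec$samples))
  rec$samples[, 20001:20150] <- rec$samples[, 20001:20150] +
    20 * typical * sin(2 * pi * 3 * (1:150) / fs + 1)
  rec$samples[, 50001:50500] <- 0
  det2 <- detect_amplitude_artifacts(rec)
  expect_gt(mean(det2$mask[1, 20001:20150]), 0.95)
  expect_true(all(det2$labels[20050:20100] == "amplitude"))
  expect_true(all(det2$mask[1, 50001:50500]))
  expect_true(all(det2$labels[50001:50500] == "zero"))
  expect_error(detect_amplitude_artifacts(
    new_recording(matrix(1, 2, 20 * fs), fs, c(0, 100))), "degenerate")
})

test_that("scratch/HVS removal recalls cortical bursts with few false positives", {
  cfg <- generator_config("rat", duration_s = 120, n_channels = 16,
                          sp_channel = 12, seed = 21,
                          artifact_spec = list(transient_rate_hz = 0,
                                               scratch_rate_hz = 0.02,
                                               zero_rate_hz = 0,
                                               saturation_rate_hz = 0))
  g <- generate_session(cfg)
  prof <- species_profile("rat")
  res <- remove_scratch_hvs(g$session$recording, prof)
  truth <- g$truth$artifact_mask[1, ]                 # same on all channels
  got <- res$mask[1, ]
  expect_gt(sum(got & truth) / sum(truth), 0.95)      # recall
  expect_lt(sum(got & !truth) / sum(!truth), 0.02)    # false positives
  # no cortical channels: no-op with warning
  rec_f <- g$session$recording
  rec_f$cortical_flag[] <- FALSE
  expect_warning(res0 <- remove_scratch_hvs(rec_f, prof), "cortical")
  expect_false(any(res0$mask))
})

test_that("quiet cortical channels yield almost no scratch masking", {
  cfg <- generator_config("rat", duration_s = 120, n_channels = 16,
                          sp_channel = 12, seed = 22)
  g <- generate_session(cfg, artifacts = FALSE)
  res <- remove_scratch_hvs(g$session$recording, species_profile("rat"))
  expect_lt(mean(res$mask[1, ]), 0.02)
})

test_that("masking is monotone: more artifacts never unmask samples", {
  g <- fix_session("rat", duration_s = 120)
  rec1 <- g$session$recording
  det1 <- detect_amplitude_artifacts(rec1)
  rec2 <- rec1
  typ <- median(abs(rec2$samples))
  rec2$samples[, 80001:80100] <- 30 * typ
  det2 <- detect_amplitude_artifacts(rec2)
  expect_true(all(det2$mask[det1$mask]))
})

test_that("tracking cleanup invalidates reflections and fills short gaps only", {
  n <- 200; fps <- 25
  base <- data.frame(frame = 1:n, t = (1:n - 1) / fps,
                     rx = seq(0, 199, by = 1), ry = 50,
                     gx = seq(0, 199, by = 1) + 40, gy = 50)
  # single-frame 200 px reflection
  tr <- base; tr$rx[100] <- tr$rx[100] + 200
  cl <- clean_tracking(tr, fps)
  expect_false(cl$valid[100])
  expect_lt(abs(cl$rx[100] - base$rx[100]), 2)     # interpolated back
  # a 1 s gap (25 frames) stays invalid
  tr2 <- base; tr2$rx[80:104] <- tr2$rx[80:104] + 200
  cl2 <- clean_tracking(tr2, fps)
  expect_true(all(is.na(cl2$rx[85:100])))
  # constant positions survive unchanged
  tr3 <- base; tr3$rx[] <- 10; tr3$gx[] <- 50
  cl3 <- clean_tracking(tr3, fps)
  expect_equal(cl3$rx, rep(10, n))
  expect_error(clean_tracking(base[1, ], fps), "2 frames")
})

test_that("speed computation is exact for constant translation", {
  n <- 100; fps <- 25
  tr <- data.frame(frame = 1:n, rx = 1:n, ry = 0, gx = 1:n + 40, gy = 0,
                   valid = TRUE)
  v <- compute_speed(tr, px_per_cm = 1, fps = fps, fs_out = 1000)
  expect_equal(median(v, na.rm = TRUE), 25)
  tr0 <- data.frame(frame = 1:n, rx = 5, ry = 0, gx = 45, gy = 0,
                    valid = TRUE)
  v0 <- compute_speed(tr0, px_per_cm = 1, fps = fps, fs_out = 1000)
  expect_equal(median(v0, na.rm = TRUE), 0)
  expect_error(compute_speed(tr, px_per_cm = NULL, fps = fps), "px_per_cm")
})

test_that("known speed is recovered through tracking synthesis and inversion", {
  cfg <- generator_config("rat", duration_s = 60, n_channels = 4,
                          sp_channel = 3, seed = 13)
  sp <- generate_speed_trace(cfg)
  px_per_cm <- 2
  tr <- synthesize_tracking(sp$speed, cfg$fs, fps = 25,
                            px_per_cm = px_per_cm, seed = 13)
  cl <- clean_tracking(tr, fps = 25)
  v <- compute_speed(cl, px_per_cm = px_per_cm, fps = 25, fs_out = cfg$fs,
                     n_out = length(sp$speed))
  ok <- !is.na(v)
  expect_gt(mean(ok), 0.95)
  rmse <- sqrt(mean((v[ok] - sp$speed[ok])^2))
  expect_lt(rmse, 1)
})

test_that("clean_session composes masking with a faithful report", {
  cfg <- generator_config("rat", duration_s = 90, n_channels = 16,
                          sp_channel = 12, seed = 31)
  g <- generate_session(cfg)                       # default artifact rates
  out <- clean_session(g$session)
  expect_true(is.numeric(out$report$masked_fraction))
  expect_equal(mean(!out$session$recording$valid_mask),
               out$report$masked_fraction)
  expect_named(out$report$masked_fraction_by_label,
               c("amplitude", "zero", "saturation", "scratch_hvs"))
})
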