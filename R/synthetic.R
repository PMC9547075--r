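## Forward model: laminar LFP + locomotion + trials with ground truth.
##
## The generator emulates the statistical structure the analysis assumes:
## speed-coupled sawtooth-like theta with a laminar amplitude/phase profile,
## broadband 1/f "large irregular activity" (LIA), species-specific state
## rules (rat: theta only during locomotion; ferret: theta in both states,
## ~1 Hz lower and more sinusoidal when immobile, enhanced in SR/SLM during
## reward consumption), an atropine mode that abolishes immobility theta,
## and injected artifacts (broadband transients, 8-12 Hz scratching bursts
## on cortical channels, runs of zeros, amplifier saturation).

#' Laminar amplitude/phase/depth profile for a synthetic probe
#'
#' Builds per-channel theta amplitude and phase-offset profiles emulating a
#' 32-site linear probe descending through the hippocampus: low-amplitude
#' cortical sites at the top, rising theta power in stratum oriens, a power
#' dip at the pyramidal cell layer (SP) where the ~180 degree phase shift
#' begins, and maximal power in stratum radiatum / lacunosum-moleculare
#' below.
#'
#' @param n_channels number of probe sites
#' @param sp_channel 1-based index of the pyramidal cell layer site
#' @param spacing_um inter-site spacing, micrometres
#' @param cortical logical: flag sites >= 600 um above SP as cortical
#' @return list with `amp` (uV), `phase_deg`, `depth_um`, `cortical`
#' @export
make_laminar_profile <- function(n_channels = 32, sp_channel = 20,
                                 spacing_um = 100, cortical = TRUE) {
  stopifnot(n_channels >= 4, sp_channel >= 2, sp_channel <= n_channels - 1)
  ch <- seq_len(n_channels)
  depth <- (ch - 1) * spacing_um
  n_cort <- if (cortical) max(0L, min(10L, sp_channel - 6L)) else 0L
  is_cort <- ch <= n_cort
  amp <- numeric(n_channels)
  for (c in ch) {
    d <- c - sp_channel             # channels relative to SP
    amp[c] <- if (c <= n_cort) 20
    else if (d <= -2) {
      ## SO ramp: rises towards a peak 2 sites above SP
      lo <- n_cort + 1
      if (c == lo && sp_channel - 2 > lo) 40
      else 40 + (120 - 40) * (c - lo) / max(1, (sp_channel - 2) - lo)
    }
    else if (d == -1) 70
    else if (d == 0) 25             # dip at the cell layer
    else if (d == 1) 90
    else if (d <= 4) 90 + (150 - 90) * (d - 1) / 3
    else 140
  }
  phase <- numeric(n_channels)
  phase[ch - sp_channel == -1] <- 30
  phase[ch - sp_channel == 0] <- 90
  phase[ch - sp_channel == 1] <- 150
  phase[ch - sp_channel >= 2] <- 180
  list(amp = amp, phase_deg = phase, depth_um = depth, cortical = is_cort,
       sp_channel = sp_channel)
}

#' Configuration for the synthetic session generator
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 32-channel probes at 100 um spacing, 1 kHz sampling, rat theta at a base
#' frequency of 7.5 Hz with speed-frequency slope 0.026 Hz/(cm/s), ferret
#' theta at 5.2 Hz with slope 0.010 and a 1 Hz downward frequency offset
#' during immobility, sawtooth skew 0.4 during locomotion (ferret immobility
#' theta is sinusoidal), 1/f^1.5 LIA, and an SR/SLM amplitude gain of 1.3
#' inside reward windows (ferret). These are generator conventions chosen so
#' pipeline estimates land in the reported ranges, not claims about animals.
#'
#' @param species_mode `"rat"` or `"ferret"`
#' @param drug_mode `"none"` or `"atropine"` (atropine abolishes theta when
#'   immobile, leaving locomotion theta untouched)
#' @param n_channels,channel_spacing_um,fs,duration_s recording geometry
#' @param sp_channel pyramidal-layer site used to build the laminar profile
#' @param theta_base_freq Hz at zero speed (default 7.5 rat / 5.2 ferret)
#' @param speed_freq_slope Hz per cm/s (default 0.026 rat / 0.010 ferret)
#' @param immobility_freq_offset Hz subtracted when immobile (ferret)
#' @param theta_amp_profile,phase_shift_profile per-channel uV / degrees;
#'   default from [make_laminar_profile()]
#' @param sawtooth_skew 0-1; 0 is a pure sinusoid
#' @param lia_exponent 1/f exponent of the LIA background
#' @param lia_amp LIA RMS amplitude, uV
#' @param reward_gain_srslm SR/SLM amplitude multiplier in reward windows
#' @param artifact_spec list of rates (events/s) and magnitudes; see source
#' @param trial_spec hold durations (5 values, 2.5-3.5 s), run plateau
#'   speed range (per-trial approach speed), reward dwell, proportion
#'   correct, number of response locations
#' @param speed_noise_sd additive speed jitter SD, cm/s (clipped at 0)
#' @param seed integer; fully determines the generated session
#' @return object of class `tq_generator_config`
#' @export
generator_config <- function(species_mode = c("ferret", "rat"),
                             drug_mode = c("none", "atropine"),
                             n_channels = 32, channel_spacing_um = 100,
                             fs = 1000, duration_s = 300, sp_channel = 20,
                             theta_base_freq = NULL, speed_freq_slope = NULL,
                             immobility_freq_offset = 1.0,
                             theta_amp_profile = NULL,
                             phase_shift_profile = NULL,
                             sawtooth_skew = 0.4, lia_exponent = 1.5,
                             lia_amp = 30, reward_gain_srslm = 1.3,
                             theta_on_threshold = 5,
                             artifact_spec = list(), trial_spec = list(),
                             speed_noise_sd = 1, seed = 1) {
  species_mode <- match.arg(species_mode)
  drug_mode <- match.arg(drug_mode)
  if (is.null(theta_base_freq))
    theta_base_freq <- if (species_mode == "rat") 7.5 else 5.2
  if (is.null(speed_freq_slope))
    speed_freq_slope <- if (species_mode == "rat") 0.026 else 0.010
  prof <- make_laminar_profile(n_channels, sp_channel, channel_spacing_um,
                               cortical = (species_mode == "rat"))
  if (is.null(theta_amp_profile)) theta_amp_profile <- prof$amp
  if (is.null(phase_shift_profile)) phase_shift_profile <- prof$phase_deg
  if (length(theta_amp_profile) != n_channels ||
      length(phase_shift_profile) != n_channels)
    stop("profile length must equal n_channels", call. = FALSE)
  if (any(theta_amp_profile < 0)) stop("amplitudes must be >= 0")
  aspec <- utils::modifyList(list(
    transient_rate_hz = 0.01, transient_gain = 20,
    scratch_rate_hz = 0.008, scratch_amp = 400,
    zero_rate_hz = 0.004, zero_len_s = 0.5,
    saturation_rate_hz = 0.002, saturation_rail = 2000
  ), artifact_spec)
  tspec <- utils::modifyList(list(
    hold_choices = seq(2.5, 3.5, by = 0.25),
    run_plateau_range = c(16, 32),
    run_plateau_dur = c(1.2, 1.8), reward_dwell_s = 2.0,
    p_correct = 0.75, n_locations = 5
  ), trial_spec)
  if (min(tspec$hold_choices) > duration_s)
    stop("infeasible trial_spec: hold longer than session", call. = FALSE)
  structure(list(
    species_mode = species_mode, drug_mode = drug_mode,
    n_channels = n_channels, channel_spacing_um = channel_spacing_um,
    fs = fs, duration_s = duration_s, sp_channel = sp_channel,
    theta_base_freq = theta_base_freq, speed_freq_slope = speed_freq_slope,
    immobility_freq_offset = immobility_freq_offset,
    theta_amp_profile = theta_amp_profile,
    phase_shift_profile = phase_shift_profile,
    depth_um = prof$depth_um, cortical = prof$cortical,
    sawtooth_skew = sawtooth_skew, lia_exponent = lia_exponent,
    lia_amp = lia_amp, reward_gain_srslm = reward_gain_srslm,
    theta_on_threshold = theta_on_threshold,
    artifact_spec = aspec, trial_spec = tspec,
    speed_noise_sd = speed_noise_sd, seed = as.integer(seed)
  ), class = "tq_generator_config")
}

## moving-average smoother with edge padding (window in samples, odd)
ma_smooth <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  k <- (w - 1) / 2
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(k + 1):(k + length(x))]
}

#' Generate a locomotion speed trace with embedded trials
#'
#' Produces a piecewise behavioural speed profile at the LFP sampling rate:
#' inter-trial wandering, an immobile Hold at the centre spout (speed ~0-2
#' cm/s, duration drawn from five values between 2.5 and 3.5 s), a Run ramp
#' to a ~25-32 cm/s plateau ending at the peripheral response, deceleration,
#' and an immobile reward dwell (speed < 5 cm/s). Additive jitter (SD
#' `speed_noise_sd`) is clipped at zero.
#'
#' @param cfg [generator_config()]
#' @return list with `speed` (cm/s at `cfg$fs`), `trials` (data frame of
#'   trial events), and `windows` (ground-truth Hold/Run/Reward windows;
#'   reward windows are the first 1 s after response with all samples
#'   < 5 cm/s, `NA` when no window qualifies)
#' @export
generate_speed_trace <- function(cfg) {
  stopifnot(inherits(cfg, "tq_generator_config"))
  set.seed(cfg$seed)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  ts <- cfg$trial_spec
  ## build (time, speed) knots piecewise, trial by trial
  kt <- 0; kv <- 0
  trials <- list()
  t_cur <- 0
  while (TRUE) {
    wander <- stats::runif(1, 2, 5)
    wander_v <- stats::runif(1, 2, 8)
    hold_dur <- sample(ts$hold_choices, 1)
    react <- 0.3
    ramp <- 0.8
    ## approach speed varies across trials (fast and slow approaches)
    plateau_v <- stats::runif(1, ts$run_plateau_range[1],
                              ts$run_plateau_range[2])
    plateau <- stats::runif(1, ts$run_plateau_dur[1], ts$run_plateau_dur[2])
    decel <- 0.4
    dwell <- ts$reward_dwell_s
    total <- wander + hold_dur + react + ramp + plateau + decel + dwell
    if (t_cur + total > cfg$duration_s) break
    hold_v <- stats::runif(1, 0.5, 1.5)
    dwell_v <- stats::runif(1, 0.5, 2.0)
    hold_start <- t_cur + wander
    onset <- hold_start + hold_dur
    response <- onset + react + ramp + plateau
    ## the run is quasi-stationary with slow speed fluctuation, not a
    ## flat plateau: knots every ~1 s with +-15% modulation
    n_rk <- max(2, round(plateau / 1.0) + 1)
    rk_t <- onset + react + ramp + plateau * seq(0, 1, length.out = n_rk)
    rk_v <- plateau_v * stats::runif(n_rk, 0.85, 1.15)
    kt <- c(kt, t_cur + wander * 0.3, t_cur + wander * 0.7, hold_start,
            onset + react, rk_t,
            response + decel, response + decel + dwell)
    kv <- c(kv, wander_v, wander_v, hold_v,
            hold_v, rk_v,
            dwell_v, dwell_v)
    correct <- stats::runif(1) < ts$p_correct
    target <- sample.int(ts$n_locations, 1)
    resp_loc <- if (correct) target else
      sample(setdiff(seq_len(ts$n_locations), target), 1)
    trials[[length(trials) + 1]] <- data.frame(
      trial = length(trials) + 1L, hold_start = hold_start,
      stimulus_onset = onset,
      modality = sample(c("A", "V"), 1), target_location = target,
      response_time = response, response_location = resp_loc,
      correct = correct, correction_trial = FALSE, aborted = FALSE)
    t_cur <- response + decel + dwell
  }
  if (length(trials) == 0)
    stop("infeasible trial_spec: duration too short for one trial",
         call. = FALSE)
  kt <- c(kt, cfg$duration_s)
  kv <- c(kv, 2)
  tgrid <- (seq_len(n) - 1) / fs
  base <- stats::approx(kt, kv, xout = tgrid, rule = 2)$y
  ## band-limited jitter (head speed is inertial): ~5 Hz, rescaled to the
  ## configured SD
  noise <- ma_smooth(stats::rnorm(n), round(0.1 * fs))
  noise <- noise / stats::sd(noise) * cfg$speed_noise_sd
  speed <- pmax(0, ma_smooth(base, round(0.15 * fs)) + noise)
  trials <- do.call(rbind, trials)
  windows <- ground_truth_windows(trials, speed, fs)
  list(speed = speed, trials = trials, windows = windows)
}

## Hold/Run windows by definition; Reward = first 1 s window after response
## with every speed sample < 5 cm/s (scanned at one-sample resolution).
ground_truth_windows <- function(trials, speed, fs, reward_thresh = 5) {
  n <- length(speed)
  win <- lapply(seq_len(nrow(trials)), function(i) {
    onset <- trials$stimulus_onset[i]
    resp <- trials$response_time[i]
    reward_start <- find_reward_window(speed, fs, resp, reward_thresh)
    data.frame(trial = trials$trial[i],
               hold_start = onset - 1.05, hold_end = onset - 0.05,
               run_start = resp - 1.0, run_end = resp,
               reward_start = reward_start,
               reward_end = reward_start + 1.0)
  })
  do.call(rbind, win)
}

## first qualifying 1 s reward window start (s), NA if none before the next
## 10 s or end of data
find_reward_window <- function(speed, fs, response_s, thresh = 5,
                               search_s = 10) {
  n <- length(speed)
  i0 <- floor(response_s * fs) + 1L
  i_max <- min(n - fs, i0 + round(search_s * fs))
  if (i0 > i_max) return(NA_real_)
  below <- speed < thresh
  ## run-length trick: count of below-threshold samples in each 1 s window
  cs <- cumsum(c(0, below))
  starts <- i0:i_max
  ok <- (cs[starts + fs] - cs[starts]) == fs
  if (!any(ok)) return(NA_real_)
  (starts[which(ok)[1]] - 1L) / fs
}

## Gaussian 1/f^alpha noise, low-pass shaped (40 Hz corner), scaled to a
## given RMS. Synthesised at fs/4 (the process is band-limited far below
## fs/8) and linearly upsampled.
lia_noise <- function(n, fs, alpha, rms) {
  dec <- 4L
  fs_lo <- fs / dec
  m <- ceiling(n / dec) + 2L
  white <- stats::rnorm(m)
  X <- stats::fft(white)
  f <- c(0, seq_len(m - 1)) * fs_lo / m
  f <- pmin(f, fs_lo - f)                   # two-sided frequency axis
  shape <- ifelse(f < 0.5, 0, f^(-alpha / 2)) / (1 + (f / 40)^4)
  x <- Re(stats::fft(X * shape, inverse = TRUE) / m)
  y <- stats::approx(seq_len(m), x, xout = 1 + (seq_len(n) - 1) / dec)$y
  y * rms / stats::sd(y)
}

## asymmetric cycle warp: u in [0,1) cycle position, r rise fraction
warp_cycle <- function(u, r) {
  ifelse(u < r, 0.5 * u / r, 0.5 + 0.5 * (u - r) / (1 - r))
}

#' Generate the multichannel LFP for a speed trace
#'
#' Per channel c the signal is
#' `A_c(t) * g(t) * wave(phi(t) + delta_c; skew) + LIA_c(t)` where the
#' instantaneous theta frequency is
#' `f(t) = base + slope * v(t) - offset * immobile(t)` (the offset applies
#' to ferret immobility only), `g(t)` is the smoothed theta-on gate (rat:
#' on only above the 5 cm/s move threshold; ferret: always on; atropine:
#' on only when moving), `wave` is an asymmetrically warped cosine (rise
#' fraction `0.5 - 0.4 * skew`; skew relaxes to 0 during ferret
#' immobility), and LIA is 1/f^alpha Gaussian noise. SR/SLM channels are
#' multiplied by `reward_gain_srslm` inside reward windows.
#'
#' @param cfg [generator_config()]
#' @param speed_out result of [generate_speed_trace()] (same cfg)
#' @return list with `recording` (see [new_recording()]) and `truth`
#'   (per-sample true frequency, theta-on gate, state, per-channel
#'   amplitude profile, layer indices, trial windows)
#' @export
generate_lfp <- function(cfg, speed_out) {
  stopifnot(inherits(cfg, "tq_generator_config"))
  set.seed(cfg$seed + 1L)
  fs <- cfg$fs
  v <- speed_out$speed
  n <- length(v)
  moving <- v > 5
  ## theta onset anticipates locomotion onset, so the generator gates
  ## theta at a lower speed than the 5 cm/s state label
  engaged <- v > cfg$theta_on_threshold
  ferret <- cfg$species_mode == "ferret"
  theta_on <- if (cfg$drug_mode == "atropine") engaged
              else if (ferret) rep(TRUE, n) else engaged
  gate <- ma_smooth(as.numeric(theta_on), round(0.1 * fs))
  f_inst <- cfg$theta_base_freq + cfg$speed_freq_slope * v
  if (ferret)
    f_inst <- f_inst - cfg$immobility_freq_offset * (1 - ma_smooth(as.numeric(moving), round(0.25 * fs)))
  f_inst <- ma_smooth(f_inst, round(0.1 * fs))
  phi <- 2 * pi * cumsum(f_inst) / fs
  skew_t <- if (ferret && cfg$drug_mode == "none")
    cfg$sawtooth_skew * ma_smooth(as.numeric(moving), round(0.25 * fs))
  else rep(cfg$sawtooth_skew, n)
  r_t <- 0.5 - 0.4 * skew_t
  ## reward gain envelope on SR/SLM channels
  rw <- speed_out$windows
  reward_ind <- numeric(n)
  for (i in seq_len(nrow(rw))) {
    if (!is.na(rw$reward_start[i])) {
      a <- floor(rw$reward_start[i] * fs) + 1L
      b <- min(n, floor((rw$reward_start[i] + cfg$trial_spec$reward_dwell_s) * fs))
      reward_ind[a:b] <- 1
    }
  }
  reward_env <- 1 + (cfg$reward_gain_srslm - 1) * ma_smooth(reward_ind, round(0.25 * fs))
  sp_depth <- cfg$depth_um[cfg$sp_channel]
  is_srslm <- cfg$depth_um >= sp_depth + 300
  apply_reward <- ferret && cfg$drug_mode == "none"
  samples <- matrix(0, nrow = cfg$n_channels, ncol = n)
  for (c in seq_len(cfg$n_channels)) {
    delta <- cfg$phase_shift_profile[c] * pi / 180
    u <- ((phi + delta) / (2 * pi)) %% 1
    wave <- cos(2 * pi * warp_cycle(u, r_t))
    amp <- cfg$theta_amp_profile[c] * gate
    if (apply_reward && is_srslm[c]) amp <- amp * reward_env
    samples[c, ] <- amp * wave +
      lia_noise(n, fs, cfg$lia_exponent, cfg$lia_amp)
  }
  recording <- new_recording(samples, fs, cfg$depth_um, cfg$cortical)
  so_ch <- cfg$sp_channel - round(200 / cfg$channel_spacing_um)
  srslm_ch <- cfg$sp_channel + round(400 / cfg$channel_spacing_um)
  truth <- list(
    freq = ifelse(theta_on, f_inst, NA_real_),
    theta_on = theta_on, gate = gate,
    state = ifelse(moving, "moving", "immobile"),
    amp_profile = cfg$theta_amp_profile,
    phase_profile = cfg$phase_shift_profile,
    layers = list(sp = cfg$sp_channel, so = so_ch,
                  srslm = if (srslm_ch <= cfg$n_channels) srslm_ch else NA),
    windows = speed_out$windows
  )
  list(recording = recording, truth = truth)
}

#' Inject artifacts into a recording
#'
#' Adds (a) broadband transients at >= 10x the typical amplitude on all
#' channels, (b) 8-12 Hz "scratching" bursts strongest on cortical-flagged
#' channels, (c) runs of exact zeros, and (d) saturation at a stated rail,
#' at the Poisson rates in `cfg$artifact_spec`. The returned ground-truth
#' mask marks every contaminated sample on every affected channel.
#'
#' @param recording a `tq_recording`
#' @param cfg [generator_config()]
#' @return list with modified `recording` and logical `mask`
#'   (channel x time, TRUE where contaminated)
#' @export
inject_artifacts <- function(recording, cfg) {
  set.seed(cfg$seed + 2L)
  fs <- recording$fs
  n <- ncol(recording$samples)
  nch <- nrow(recording$samples)
  dur_s <- n / fs
  mask <- matrix(FALSE, nch, n)
  spec <- cfg$artifact_spec
  typical <- stats::median(abs(recording$samples))
  draw_events <- function(rate) {
    k <- stats::rpois(1, rate * dur_s)
    if (k == 0) numeric(0) else sort(stats::runif(k, 1, dur_s - 3))
  }
  for (t0 in draw_events(spec$transient_rate_hz)) {
    len <- round(stats::runif(1, 0.05, 0.3) * fs)
    idx <- floor(t0 * fs) + seq_len(len)
    burst <- spec$transient_gain * typical *
      ma_smooth(stats::rnorm(len), 5) * sin(pi * seq_len(len) / len)
    recording$samples[, idx] <- sweep(recording$samples[, idx, drop = FALSE],
                                      2, burst, "+")
    mask[, idx] <- TRUE
  }
  for (t0 in draw_events(spec$scratch_rate_hz)) {
    len <- round(stats::runif(1, 0.5, 2.0) * fs)
    idx <- floor(t0 * fs) + seq_len(len)
    f <- stats::runif(1, 8, 12)
    tone <- sin(2 * pi * f * seq_len(len) / fs) * sin(pi * seq_len(len) / len)
    gain <- ifelse(recording$cortical_flag, 1, 0.3) * spec$scratch_amp
    recording$samples[, idx] <- recording$samples[, idx, drop = FALSE] +
      outer(gain, tone)
    mask[, idx] <- TRUE
  }
  for (t0 in draw_events(spec$zero_rate_hz)) {
    idx <- floor(t0 * fs) + seq_len(round(spec$zero_len_s * fs))
    recording$samples[, idx] <- 0
    mask[, idx] <- TRUE
  }
  for (t0 in draw_events(spec$saturation_rate_hz)) {
    idx <- floor(t0 * fs) + seq_len(round(0.2 * fs))
    recording$samples[, idx] <- spec$saturation_rail
    mask[, idx] <- TRUE
  }
  list(recording = recording, mask = mask)
}

#' Generate a complete synthetic session
#'
#' Composes [generate_speed_trace()], [generate_lfp()] and
#' [inject_artifacts()] into a [new_session()] plus its ground truth.
#'
#' @param cfg [generator_config()]
#' @param artifacts logical; inject artifacts at the configured rates
#' @return list with `session` and `truth` (truth gains `artifact_mask`)
#' @export
generate_session <- function(cfg, artifacts = TRUE) {
  sp <- generate_speed_trace(cfg)
  lfp <- generate_lfp(cfg, sp)
  art_mask <- matrix(FALSE, cfg$n_channels, ncol(lfp$recording$samples))
  rec <- lfp$recording
  if (artifacts) {
    inj <- inject_artifacts(rec, cfg)
    rec <- inj$recording
    art_mask <- inj$mask
  }
  truth <- lfp$truth
  truth$artifact_mask <- art_mask
  session <- new_session(
    recording = rec,
    speed = sp$speed,
    trials = sp$trials,
    species_profile = species_profile(cfg$species_mode),
    meta = list(subject = "synthetic", session = sprintf("seed%d", cfg$seed),
                drug = cfg$drug_mode, generator_seed = cfg$seed,
                species_mode = cfg$species_mode,
                generator_config = as.character(jsonlite::toJSON(
                  unclass(cfg), auto_unbox = TRUE, digits = NA)))
  )
  list(session = session, truth = truth)
}

#' Synthesize LED tracking pixels from a speed trace
#'
#' Inverse of the speed computation: integrates the speed into a smooth 2-D
#' head path (random-walk heading), places two LEDs at a fixed separation
#' along the heading, and samples at the camera frame rate. Used to test
#' tracking cleanup and speed recovery end to end.
#'
#' @param speed cm/s at `fs`
#' @param fs LFP sampling rate, Hz
#' @param fps camera frame rate
#' @param px_per_cm pixel scale
#' @param led_sep_px LED separation in pixels
#' @param seed integer
#' @return data frame: `frame`, `t`, `rx`, `ry`, `gx`, `gy`
#' @export
synthesize_tracking <- function(speed, fs, fps = 25, px_per_cm = 2,
                                led_sep_px = 40, seed = 1) {
  set.seed(seed)
  n <- length(speed)
  ## integrate the path at the full rate, then sample camera frames
  heading <- cumsum(stats::rnorm(n, 0, 0.08 * sqrt(fps / fs)))
  x <- cumsum(speed / fs * px_per_cm * cos(heading))
  y <- cumsum(speed / fs * px_per_cm * sin(heading))
  n_frames <- floor(n / fs * fps)
  idx <- round((seq_len(n_frames) - 1) / fps * fs) + 1
  data.frame(frame = seq_len(n_frames), t = (seq_len(n_frames) - 1) / fps,
             rx = x[idx] + led_sep_px / 2 * cos(heading[idx]),
             ry = y[idx] + led_sep_px / 2 * sin(heading[idx]),
             gx = x[idx] - led_sep_px / 2 * cos(heading[idx]),
             gy = y[idx] - led_sep_px / 2 * sin(heading[idx]))
}

#' Simulate an epoch-level peak-range table from a mixed-effects model
#'
#' Draws a balanced table of 1 s epoch peak-range values directly from a
#' nested random-intercept model, for calibration and parameter-recovery
#' simulations of the statistical stage (no LFP synthesis involved).
#'
#' @param n_per_cell epochs per ID x session x state x channel cell
#' @param beta named fixed effects: `intercept`, `mov` (moving vs immobile),
#'   `species` (rat vs ferret), `interaction` (mov x species), `chan`
#' @param sd_id,sd_session,sd_noise random-intercept and residual SDs
#' @param n_id,n_session group sizes per species
#' @param seed integer
#' @return data frame with columns `PeakRange`, `MovFlag`, `Species`,
#'   `Chan`, `ID`, `Session`
#' @export
simulate_epoch_table <- function(n_per_cell = 20,
                                 beta = c(intercept = 0.3, mov = 0.1,
                                          species = 0.05, interaction = 0.15,
                                          chan = 0.02),
                                 sd_id = 0.05, sd_session = 0.03,
                                 sd_noise = 0.15, n_id = 3, n_session = 3,
                                 seed = 1) {
  set.seed(seed)
  g <- expand.grid(rep = seq_len(n_per_cell),
                   MovFlag = c("immobile", "moving"),
                   Chan = c("SO", "SRSLM"),
                   Session = paste0("s", seq_len(n_session)),
                   ID = paste0("id", seq_len(n_id)),
                   Species = c("rat", "ferret"),
                   stringsAsFactors = FALSE)
  g$ID <- paste(g$Species, g$ID, sep = "_")
  id_eff <- stats::rnorm(length(unique(g$ID)), 0, sd_id)
  names(id_eff) <- unique(g$ID)
  ses <- unique(paste(g$ID, g$Session))
  ses_eff <- stats::rnorm(length(ses), 0, sd_session)
  names(ses_eff) <- ses
  mov <- as.numeric(g$MovFlag == "moving")
  rat <- as.numeric(g$Species == "rat")
  chan <- as.numeric(g$Chan == "SRSLM")
  g$PeakRange <- beta["intercept"] + beta["mov"] * mov +
    beta["species"] * rat + beta["interaction"] * mov * rat +
    beta["chan"] * chan + id_eff[g$ID] +
    ses_eff[paste(g$ID, g$Session)] + stats::rnorm(nrow(g), 0, sd_noise)
  g$MovFlag <- factor(g$MovFlag, levels = c("immobile", "moving"))
  g$Species <- factor(g$Species, levels = c("rat", "ferret"))
  g$Chan <- factor(g$Chan)
  g$ID <- factor(g$ID)
  g$Session <- factor(g$Session)
  g
}
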