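## Channel exclusion, artifact masking and head-tracking cleanup.

#' Welch power spectral density
#'
#' Welch's method with a Hanning window, nfft 4096 and 50% overlap
#' (segment length = nfft). Any segment containing a masked (NA) sample is
#' dropped rather than interpolated.
#'
#' @param signal single-channel trace (NA where masked)
#' @param fs sampling rate, Hz
#' @param nfft segment/FFT length
#' @return data frame with `freq` (Hz) and `power_db` (10*log10 of the
#'   one-sided density, uV^2/Hz)
#' @export
compute_psd <- function(signal, fs, nfft = 4096) {
  n <- length(signal)
  if (n < nfft)
    stop("need at least nfft valid samples", call. = FALSE)
  step <- nfft / 2
  starts <- seq(1, n - nfft + 1, by = step)
  win <- signal::hanning(nfft)
  u <- sum(win^2)
  acc <- numeric(nfft / 2 + 1)
  used <- 0L
  for (s in starts) {
    seg <- signal[s:(s + nfft - 1)]
    if (anyNA(seg)) next
    seg <- (seg - mean(seg)) * win
    X <- stats::fft(seg)
    p <- Mod(X[1:(nfft / 2 + 1)])^2 / (fs * u)
    p[2:(nfft / 2)] <- 2 * p[2:(nfft / 2)]
    acc <- acc + p
    used <- used + 1L
  }
  if (used == 0L)
    stop("all segments contain masked samples", call. = FALSE)
  data.frame(freq = (0:(nfft / 2)) * fs / nfft,
             power_db = 10 * log10(acc / used))
}

## dB prominence of the in-band PSD peak above the interpolated background
## (median dB in 2 Hz flanks on either side of the band)
band_peak_prominence <- function(psd, band, flank = 2) {
  inb <- psd$freq >= band[1] & psd$freq <= band[2]
  lo <- psd$freq >= band[1] - flank & psd$freq < band[1]
  hi <- psd$freq > band[2] & psd$freq <= band[2] + flank
  bg <- mean(c(stats::median(psd$power_db[lo]),
               stats::median(psd$power_db[hi])), na.rm = TRUE)
  max(psd$power_db[inb]) - bg
}

#' Channel inclusion by spectral criteria
#'
#' Excludes channels whose theta-band PSD peak prominence falls below the
#' species threshold (4 dB rat, 2 dB ferret) or whose 50 Hz power exceeds
#' the theta peak by more than the configured margin. An all-excluded
#' outcome is valid and flagged.
#'
#' @param recording a `tq_recording`
#' @param profile a [species_profile()]
#' @return list: `include` (logical per channel), `reasons` (character per
#'   channel: `"ok"`, `"low_theta"` or `"mains"`), `all_excluded` flag
#' @export
select_channels <- function(recording, profile) {
  nch <- nrow(recording$samples)
  include <- logical(nch)
  reasons <- character(nch)
  for (c in seq_len(nch)) {
    x <- recording$samples[c, ]
    x[!recording$valid_mask[c, ]] <- NA
    psd <- compute_psd(x, recording$fs, profile$psd_nfft)
    theta_prom <- band_peak_prominence(psd, profile$psd_theta_band)
    theta_peak <- max(psd$power_db[psd$freq >= profile$psd_theta_band[1] &
                                   psd$freq <= profile$psd_theta_band[2]])
    mains_peak <- max(psd$power_db[abs(psd$freq - profile$mains_hz) <= 1])
    if (theta_prom < profile$theta_power_exclusion_db) {
      reasons[c] <- "low_theta"
    } else if (mains_peak >= theta_peak + profile$mains_margin_db) {
      reasons[c] <- "mains"
    } else {
      include[c] <- TRUE
      reasons[c] <- "ok"
    }
  }
  list(include = include, reasons = reasons, all_excluded = !any(include))
}

#' Histogram mode of a continuous distribution
#'
#' Freedman-Diaconis binning; the mode is the centre of the fullest bin.
#' Deterministic and scale-aware.
#'
#' @param x numeric vector
#' @return scalar mode estimate
#' @export
dist_mode <- function(x) {
  x <- x[is.finite(x)]
  iqr <- stats::IQR(x)
  if (iqr == 0) return(stats::median(x))
  h <- 2 * iqr / length(x)^(1 / 3)
  breaks <- seq(min(x), max(x) + h, by = h)
  ct <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
  i <- which.max(ct)
  (breaks[i] + breaks[i + 1]) / 2
}

## expand TRUE runs of a logical vector by pad samples and bridge gaps
## shorter than gap samples
dilate_runs <- function(flag, pad = 0L, gap = 0L) {
  n <- length(flag)
  if (pad > 0) {
    idx <- which(flag)
    if (length(idx)) {
      lo <- pmax(1L, idx - pad)
      hi <- pmin(n, idx + pad)
      out <- logical(n)
      for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
      flag <- out
    }
  }
  if (gap > 0 && any(flag)) {
    r <- rle(flag)
    short <- !r$values & r$lengths <= gap
    ## don't bridge leading/trailing clean runs
    short[c(1, length(short))] <- FALSE
    r$values[short] <- TRUE
    flag <- inverse.rle(r)
  }
  flag
}

#' Detect large-amplitude artifacts, zeros and saturation
#'
#' The cross-channel mean absolute amplitude is thresholded at 10x the
#' mode of its distribution; supra-threshold runs are masked on all
#' channels (artifacts of this kind appear probe-wide). Runs of exact
#' zeros and rail saturation are masked with their own labels.
#'
#' @param recording a `tq_recording`
#' @param factor threshold multiplier on the amplitude mode
#' @param rail saturation rail in uV (`NULL` to use the observed extreme
#'   when it repeats)
#' @param pad_s mask padding around supra-threshold runs, s
#' @param gap_s bridge clean gaps shorter than this between masked runs, s
#' @return list: `mask` (logical channel x time), `labels` (character
#'   vector over time: `""`, `"amplitude"`, `"zero"`, `"saturation"`),
#'   `threshold`
#' @export
detect_amplitude_artifacts <- function(recording, factor = 10, rail = NULL,
                                       pad_s = 0.05, gap_s = 0.05) {
  fs <- recording$fs
  x <- recording$samples
  if (ncol(x) < 10 * fs)
    stop("need at least 10 s of data", call. = FALSE)
  mean_amp <- colMeans(abs(x), na.rm = TRUE)
  if (stats::sd(mean_amp, na.rm = TRUE) == 0)
    stop("degenerate (constant) signal", call. = FALSE)
  thr <- dist_mode(mean_amp) * factor
  amp_flag <- dilate_runs(!is.na(mean_amp) & mean_amp > thr,
                          pad = round(pad_s * fs), gap = round(gap_s * fs))
  zero_flag <- dilate_runs(colSums(x == 0, na.rm = TRUE) == nrow(x) &
                             !is.na(mean_amp), gap = 0L)
  ## only sustained zero runs (>= 10 ms) count as dropouts
  r <- rle(zero_flag)
  r$values[r$values & r$lengths < round(0.01 * fs)] <- FALSE
  zero_flag <- inverse.rle(r)
  sat_flag <- logical(ncol(x))
  if (!is.null(rail)) {
    sat_flag <- colSums(abs(x) >= rail, na.rm = TRUE) > 0
  } else {
    ## a repeated exact extreme value is read as the rail
    mx <- max(abs(x), na.rm = TRUE)
    if (sum(abs(x) == mx, na.rm = TRUE) > 2 * nrow(x))
      sat_flag <- colSums(abs(x) == mx, na.rm = TRUE) > 0
  }
  sat_flag <- dilate_runs(sat_flag, pad = round(pad_s * fs),
                          gap = round(gap_s * fs))
  labels <- character(ncol(x))
  labels[amp_flag] <- "amplitude"
  labels[zero_flag] <- "zero"
  labels[sat_flag] <- "saturation"
  any_flag <- amp_flag | zero_flag | sat_flag
  mask <- matrix(rep(any_flag, each = nrow(x)), nrow(x))
  list(mask = mask, labels = labels, threshold = thr)
}

#' Detect scratching and high-voltage spike-wave epochs
#'
#' Rat-specific cleanup: 8-12 Hz scratching artifacts (and HVS events)
#' dominate cortical channels. Each channel is filtered 6-13 Hz with a
#' zero-lag FIR (order 500 ms), 6-13 Hz power is taken from the Hilbert
#' envelope, the median across cortical channels is thresholded at
#' `factor` x the mode of its distribution, and supra-threshold sections
#' are masked on all channels. Sessions without cortical channels (ferret)
#' yield an empty mask with a warning.
#'
#' @param recording a `tq_recording`
#' @param profile a [species_profile()]
#' @param factor threshold multiplier on the power mode
#' @return list: `mask` (channel x time), `labels` (`"scratch_hvs"` runs),
#'   `threshold` (or NA for the no-op case)
#' @export
remove_scratch_hvs <- function(recording, profile, factor = NULL) {
  nch <- nrow(recording$samples)
  n <- ncol(recording$samples)
  if (!any(recording$cortical_flag)) {
    warning("no cortical channels flagged; scratch/HVS removal skipped")
    return(list(mask = matrix(FALSE, nch, n), labels = character(n),
                threshold = NA_real_))
  }
  if (is.null(factor)) factor <- profile$scratch_threshold_factor
  fs <- recording$fs
  b <- fir_bandpass(profile$scratch_band, profile$scratch_fir_order_s, fs)
  cort <- which(recording$cortical_flag)
  pow <- matrix(NA_real_, length(cort), n)
  for (k in seq_along(cort)) {
    x <- recording$samples[cort[k], ]
    x[is.na(x)] <- 0
    xf <- fir_zero_lag(b, x)
    xf[is.na(xf)] <- 0
    pow[k, ] <- Mod(analytic_signal(xf))^2
  }
  med_pow <- apply(pow, 2, stats::median)
  thr <- dist_mode(med_pow) * factor
  ## generous padding: burst onsets/offsets taper through the threshold
  flag <- dilate_runs(med_pow > thr, pad = round(0.15 * fs),
                      gap = round(0.1 * fs))
  labels <- character(n)
  labels[flag] <- "scratch_hvs"
  mask <- matrix(rep(flag, each = nch), nch)
  list(mask = mask, labels = labels, threshold = thr)
}

#' Apply an artifact mask to a session
#'
#' Masked samples are replaced by NA and `valid_mask` is cleared; masking
#' is monotone (already-masked samples stay masked).
#'
#' @param session a `tq_session`
#' @param mask logical channel x time
#' @return the updated session
#' @export
apply_artifact_mask <- function(session, mask) {
  r <- session$recording
  stopifnot(identical(dim(mask), dim(r$samples)))
  r$samples[mask] <- NA_real_
  r$valid_mask <- r$valid_mask & !mask
  session$recording <- r
  session
}

#' Clean a session end to end
#'
#' Runs channel selection, amplitude/zero/saturation masking and (for
#' sessions with cortical channels) scratch/HVS removal, applies the
#' combined mask, and attaches a report.
#'
#' @param session a `tq_session`
#' @return list: `session` (masked), `report` (channel inclusion, masked
#'   fraction per label, thresholds)
#' @export
clean_session <- function(session) {
  profile <- session$species_profile
  sel <- select_channels(session$recording, profile)
  amp <- detect_amplitude_artifacts(session$recording)
  scr <- if (any(session$recording$cortical_flag))
    remove_scratch_hvs(session$recording, profile)
  else list(mask = matrix(FALSE, nrow(session$recording$samples),
                          ncol(session$recording$samples)),
            labels = character(ncol(session$recording$samples)),
            threshold = NA_real_)
  mask <- amp$mask | scr$mask
  session <- apply_artifact_mask(session, mask)
  n <- ncol(session$recording$samples)
  report <- list(
    include = sel$include, reasons = sel$reasons,
    all_excluded = sel$all_excluded,
    masked_fraction = mean(mask),
    masked_fraction_by_label = c(
      amplitude = mean(amp$labels == "amplitude"),
      zero = mean(amp$labels == "zero"),
      saturation = mean(amp$labels == "saturation"),
      scratch_hvs = mean(scr$labels == "scratch_hvs")),
    amplitude_threshold = amp$threshold,
    scratch_threshold = scr$threshold)
  list(session = session, report = report)
}

#' Clean LED head-tracking data
#'
#' Invalidates frames violating the jump (> `max_jump_px` per frame) or
#' LED-separation (outside `sep_range_px`) constraints, linearly
#' interpolates across invalid gaps shorter than `max_gap_s`, and median
#' filters each coordinate (width 5). Longer gaps stay invalid.
#'
#' @param tracking data frame with `rx, ry, gx, gy` pixel columns and a
#'   frame rate attribute or `fps` argument
#' @param fps frames per second
#' @param max_jump_px per-frame travel limit
#' @param sep_range_px allowed LED separation (rig-dependent)
#' @param max_gap_s longest gap filled by interpolation
#' @return tracking data frame with cleaned coordinates and `valid` flag
#' @export
clean_tracking <- function(tracking, fps, max_jump_px = 50,
                           sep_range_px = c(30, 50), max_gap_s = 0.66) {
  n <- nrow(tracking)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  led <- as.matrix(tracking[, c("rx", "ry", "gx", "gy")])
  sep <- sqrt((led[, 1] - led[, 3])^2 + (led[, 2] - led[, 4])^2)
  bad_sep <- sep < sep_range_px[1] | sep > sep_range_px[2]
  jump <- function(x, y) c(0, sqrt(diff(x)^2 + diff(y)^2))
  bad_jump <- jump(led[, 1], led[, 2]) > max_jump_px |
    jump(led[, 3], led[, 4]) > max_jump_px
  bad <- bad_sep | bad_jump | !stats::complete.cases(led)
  max_gap <- floor(max_gap_s * fps)
  out <- tracking
  valid <- !bad
  for (col in c("rx", "ry", "gx", "gy")) {
    x <- tracking[[col]]
    x[bad] <- NA
    ## interpolate only across short gaps
    if (any(bad) && any(!bad)) {
      r <- rle(is.na(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      filled <- stats::approx(which(!is.na(x)), x[!is.na(x)],
                              xout = seq_len(n), rule = 1)$y
      for (k in which(r$values)) {
        if (r$lengths[k] <= max_gap)
          x[starts[k]:ends[k]] <- filled[starts[k]:ends[k]]
      }
    }
    x[!is.na(x)] <- stats::runmed(x[!is.na(x)], 5)
    out[[col]] <- x
  }
  ## `valid` records original frame validity; repaired (interpolated)
  ## frames keep valid = FALSE but carry usable coordinates
  out$valid <- valid
  out
}

#' Head speed from cleaned tracking
#'
#' Head position is the mean of the two LED positions; speed is the
#' per-frame displacement scaled to cm/s and aligned to the LFP time base
#' by interpolation. Invalid frames propagate as NA speed.
#'
#' @param tracking cleaned tracking (see [clean_tracking()])
#' @param px_per_cm pixel scale (required; rig metadata)
#' @param fps camera frame rate
#' @param fs_out output sampling rate (LFP rate), Hz
#' @param n_out output length in samples (defaults to full span)
#' @return numeric speed trace, cm/s at `fs_out`, NA where invalid
#' @export
compute_speed <- function(tracking, px_per_cm, fps, fs_out = 1000,
                          n_out = NULL) {
  if (is.null(px_per_cm) || !is.finite(px_per_cm) || px_per_cm <= 0)
    stop("config error: px_per_cm must be a positive number", call. = FALSE)
  hx <- (tracking$rx + tracking$gx) / 2
  hy <- (tracking$ry + tracking$gy) / 2
  disp <- c(NA, sqrt(diff(hx)^2 + diff(hy)^2))
  ## NA coordinates (frames left unrepaired by cleanup) propagate via disp
  v_frame <- disp * fps / px_per_cm
  ## short moving average undoes the staircase left in frame-to-frame
  ## displacement by the position median filter
  ok <- !is.na(v_frame)
  if (sum(ok) > 5) v_frame[ok] <- ma_smooth(v_frame[ok], 5)
  tf <- (seq_along(v_frame) - 1) / fps
  if (is.null(n_out)) n_out <- floor(max(tf) * fs_out) + 1
  t_out <- (seq_len(n_out) - 1) / fs_out
  ok <- !is.na(v_frame)
  if (sum(ok) < 2) return(rep(NA_real_, n_out))
  v <- stats::approx(tf[ok], v_frame[ok], xout = t_out, rule = 2)$y
  ## re-impose invalidity over long invalid stretches
  inv <- stats::approx(tf, as.numeric(!ok), xout = t_out, method = "constant",
                       rule = 2)$y
  v[inv > 0] <- NA
  v
}
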