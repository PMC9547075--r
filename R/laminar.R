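## Depth profiles of theta power/phase, speed-theta regressions, and
## hippocampal layer assignment.

## circular mean of angles in degrees
circ_mean_deg <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  (atan2(mean(sin(x * pi / 180)), mean(cos(x * pi / 180))) * 180 / pi) %% 360
}

## wrap to (-180, 180]
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Theta depth profile across probe channels
#'
#' Runs the theta band-pass and peak-trough estimator on every requested
#' channel, restricts to locomotion samples (speed above the species
#' locomotion threshold, default 10 cm/s), and reports per-channel median
#' theta power (with IQR), the circular-mean phase shift relative to the
#' top analysed channel (0 by definition there), and per-channel
#' speed-frequency and speed-power regression slopes with
#' Bonferroni-corrected significance flags.
#'
#' @param session a `tq_session` with a speed trace
#' @param channels channel indices (default all)
#' @param min_locomotion_s minimum locomotion data required, s
#' @param regressions also fit the per-channel speed regressions (skip for
#'   pure power/phase profiling, e.g. layer assignment)
#' @return data frame, one row per channel: `channel`, `depth_um`,
#'   `power_median`, `power_iqr`, `phase_shift_deg`, `freq_slope`,
#'   `freq_slope_sig`, `power_slope`, `power_slope_sig`
#' @export
theta_depth_profile <- function(session, channels = NULL,
                                min_locomotion_s = 60,
                                regressions = TRUE) {
  stopifnot(inherits(session, "tq_session"), !is.null(session$speed))
  profile <- session$species_profile
  fs <- session$recording$fs
  if (is.null(channels)) channels <- seq_len(nrow(session$recording$samples))
  speed <- session$speed
  loco <- !is.na(speed) & speed > profile$locomotion_threshold
  if (sum(loco) / fs < min_locomotion_s)
    stop("insufficient locomotion data (need >= ", min_locomotion_s, " s)",
         call. = FALSE)
  alpha <- bonferroni_alpha(length(channels))
  inst_all <- vector("list", length(channels))
  for (k in seq_along(channels)) {
    x <- session$recording$samples[channels[k], ]
    x[!session$recording$valid_mask[channels[k], ]] <- NA
    filt <- bandpass_theta(x, profile, fs)
    ext <- detect_extrema(filt)
    inst_all[[k]] <- instantaneous_theta(ext, length(x), fs)
  }
  top <- inst_all[[1]]
  out <- data.frame(channel = channels,
                    depth_um = session$recording$channel_depth[channels],
                    power_median = NA_real_, power_iqr = NA_real_,
                    phase_shift_deg = NA_real_,
                    freq_slope = NA_real_, freq_slope_sig = NA,
                    power_slope = NA_real_, power_slope_sig = NA)
  for (k in seq_along(channels)) {
    inst <- inst_all[[k]]
    out$power_median[k] <- stats::median(inst$power[loco], na.rm = TRUE)
    out$power_iqr[k] <- stats::IQR(inst$power[loco], na.rm = TRUE)
    dphi <- wrap180(inst$phase[loco] - top$phase[loco])
    out$phase_shift_deg[k] <- if (k == 1) 0 else wrap180(circ_mean_deg(dphi))
    if (!regressions) next
    rf <- speed_theta_regression(inst, speed, fs, "frequency", profile)
    rp <- speed_theta_regression(inst, speed, fs, "power", profile)
    if (!is.null(rf)) {
      out$freq_slope[k] <- rf$beta1
      out$freq_slope_sig[k] <- is.finite(rf$p) && rf$p < alpha
    }
    if (!is.null(rp)) {
      out$power_slope[k] <- rp$beta1
      out$power_slope_sig[k] <- is.finite(rp$p) && rp$p < alpha
    }
  }
  out
}

#' Speed-theta regression on binned epoch medians
#'
#' Speed and the target (instantaneous frequency or power) are reduced to
#' medians over 250 ms epochs during locomotion (epoch median speed above
#' the locomotion threshold); epochs above the 90th speed percentile are
#' excluded; remaining epochs are binned at 5 cm/s and ordinary least
#' squares is fitted to the per-bin medians, with p from the slope t-test.
#'
#' @param inst result of [instantaneous_theta()]
#' @param speed speed trace, cm/s, same time base
#' @param fs sampling rate, Hz
#' @param target `"frequency"` or `"power"`
#' @param profile a [species_profile()]
#' @param epoch_s reduction epoch, s
#' @param bin_cm_s speed bin width, cm/s
#' @return list: `beta0`, `beta1`, `p`, `r_squared`, `n_bins`,
#'   `bin_edges`; or NULL (with a warning) when < 3 usable bins
#' @export
speed_theta_regression <- function(inst, speed, fs, target = c("frequency",
                                                               "power"),
                                   profile, epoch_s = 0.25, bin_cm_s = 5) {
  target <- match.arg(target)
  len <- round(epoch_s * fs)
  n_ep <- floor(length(speed) / len)
  y_all <- inst[[target]]
  ep_v <- ep_y <- rep(NA_real_, n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1) * len + 1):(i * len)
    ok <- !is.na(y_all[idx]) & !is.na(speed[idx])
    if (mean(ok) < 0.5) next
    ## "epochs during locomotion": the whole epoch must be locomotor, so
    ## epochs straddling a movement (and theta) onset are excluded
    if (min(speed[idx], na.rm = TRUE) <= profile$move_threshold) next
    ep_v[i] <- stats::median(speed[idx][ok])
    ep_y[i] <- stats::median(y_all[idx][ok])
  }
  keep <- !is.na(ep_v) & !is.na(ep_y) & ep_v > profile$locomotion_threshold
  ep_v <- ep_v[keep]; ep_y <- ep_y[keep]
  if (length(ep_v) > 0) {
    p90 <- stats::quantile(ep_v, 0.9)
    ep_y <- ep_y[ep_v <= p90]
    ep_v <- ep_v[ep_v <= p90]
  }
  if (length(ep_v) < 3) {
    warning("too few locomotion epochs for regression")
    return(NULL)
  }
  edges <- seq(floor(min(ep_v) / bin_cm_s) * bin_cm_s,
               ceiling(max(ep_v) / bin_cm_s) * bin_cm_s, by = bin_cm_s)
  bin <- findInterval(ep_v, edges, rightmost.closed = TRUE)
  ## per-bin medians of both variables: edge bins are rarely centred on
  ## their midpoint, so the bin's median speed is the honest abscissa
  y <- as.numeric(tapply(ep_y, bin, stats::median))
  x <- as.numeric(tapply(ep_v, bin, stats::median))
  if (length(y) < 3) {
    warning("fewer than 3 usable speed bins")
    return(NULL)
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(beta0 = unname(stats::coef(fit)[1]), beta1 = unname(stats::coef(fit)[2]),
       p = s$coefficients[2, 4], r_squared = s$r.squared,
       n_bins = length(y), bin_edges = edges)
}

#' Assign hippocampal layers from a depth profile
#'
#' The pyramidal cell layer (SP) is the power-minimising channel within
#' the zone where the channel-to-channel phase-shift gradient first
#' exceeds `grad_threshold` degrees per channel sustained over at least
#' two channel steps. Stratum oriens is 200 um above SP and SR/SLM 400 um
#' below, located via channel depth. When no dip-plus-shift co-occurrence
#' exists (probe did not cross the layer), the fallback takes the
#' highest-theta-power channel as SO and leaves SR/SLM unassigned.
#'
#' @param profile data frame from [theta_depth_profile()] (>= 8 channels)
#' @param grad_threshold phase gradient threshold, degrees/channel
#' @return list: `sp`, `so`, `srslm` (channel indices or NA), `method`
#'   (`"profile"` or `"power-peak fallback"`)
#' @export
estimate_layers <- function(profile, grad_threshold = 20) {
  stopifnot(nrow(profile) >= 8)
  ph <- profile$phase_shift_deg
  g <- abs(wrap180(diff(ph)))
  big <- g > grad_threshold
  sustained <- which(big[-length(big)] & big[-1])
  fallback <- function(msg = NULL) {
    if (!is.null(msg)) warning(msg)
    list(sp = NA_integer_, so = profile$channel[which.max(profile$power_median)],
         srslm = NA_integer_, method = "power-peak fallback")
  }
  if (length(sustained) == 0) {
    return(fallback(if (all(g < 5)) "flat phase profile; using power peak"))
  }
  z0 <- sustained[1]
  z1 <- z0
  while (z1 < length(big) && big[z1 + 1]) z1 <- z1 + 1
  zone <- z0:min(z1 + 1, nrow(profile))     # channels spanned by the shift
  sp_row <- zone[which.min(profile$power_median[zone])]
  sp <- profile$channel[sp_row]
  spacing <- stats::median(diff(profile$depth_um))
  sp_depth <- profile$depth_um[sp_row]
  find_at <- function(target_depth) {
    i <- which(abs(profile$depth_um - target_depth) < spacing / 2)
    if (length(i) == 1) profile$channel[i] else NA_integer_
  }
  list(sp = sp, so = find_at(sp_depth - 200), srslm = find_at(sp_depth + 400),
       method = "profile")
}

#' Ripple-band power profile across channels
#'
#' Band-passed (default 150-250 Hz) RMS power per channel, reported as a
#' confirmation aid for the cell-layer position only; it never overrides
#' [estimate_layers()].
#'
#' @param recording a `tq_recording`
#' @param band length-2 Hz
#' @param order_s FIR order, s
#' @return data frame: `channel`, `depth_um`, `rms`
#' @export
ripple_power_profile <- function(recording, band = c(150, 250),
                                 order_s = 0.05) {
  if (band[1] >= band[2]) stop("config error: band lo >= hi", call. = FALSE)
  if (recording$fs < 2 * band[2])
    stop("sampling rate too low for the ripple band", call. = FALSE)
  b <- fir_bandpass(band, order_s, recording$fs)
  rms <- vapply(seq_len(nrow(recording$samples)), function(c) {
    x <- recording$samples[c, ]
    x[!recording$valid_mask[c, ]] <- NA
    x[is.na(x)] <- 0
    y <- fir_zero_lag(b, x)
    sqrt(mean(y^2, na.rm = TRUE))
  }, numeric(1))
  data.frame(channel = seq_len(nrow(recording$samples)),
             depth_um = recording$channel_depth, rms = rms)
}
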