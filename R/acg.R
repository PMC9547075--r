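## Autocorrelogram matched-sinusoid statistic ("peak range").
##
## One-second LFP epochs are autocorrelated, compared against a bank of
## sinusoid autocorrelograms on a 0.1 Hz grid by normalised Euclidean
## distance, and the range of the first autocorrelogram peak (peak value
## minus the mean of the two flanking troughs) is normalised by the same
## measurement on the matched sinusoid. Periodic in-band signals score ~1,
## white noise ~0.

#' High-pass and 50 Hz notch prefilter for the autocorrelogram stage
#'
#' Chebyshev type II high-pass (rat: order 6, 80 dB, 2 Hz passband edge;
#' ferret: order 4, 80 dB, 1 Hz) followed by a 14th-order Chebyshev
#' type II band-stop (60 dB, stopband 49-51 Hz), both executed zero-phase
#' (forward-backward) as second-order sections. NA (masked) gaps are
#' filtered segment-wise and preserved.
#'
#' @param signal single-channel trace
#' @param profile a [species_profile()]
#' @param fs sampling rate, Hz
#' @return filtered trace, NA where input was NA
#' @export
prefilter_for_acg <- function(signal, profile, fs) {
  hp <- design_cheby2_hp_passband(profile$hp_filter$order,
                                  profile$hp_filter$rs_db,
                                  profile$hp_filter$passband_hz, fs)
  notch <- design_cheby2_sos(profile$notch_spec$order / 2,
                             profile$notch_spec$rs_db,
                             profile$notch_spec$stopband_hz, fs, "stop")
  out <- rep(NA_real_, length(signal))
  segs <- unmasked_segments(!is.na(signal))
  min_len <- 3 * fs / profile$hp_filter$passband_hz  # skip sub-transient bits
  for (s in seq_len(nrow(segs))) {
    idx <- segs$start[s]:segs$end[s]
    if (length(idx) < min_len) next
    out[idx] <- sos_filtfilt(notch, sos_filtfilt(hp, signal[idx]))
  }
  out
}

#' Segment a trace and speed into aligned 1 s epochs
#'
#' Non-overlapping half-open windows `[t, t + epoch_len)`. Epochs
#' containing any masked sample are marked invalid. Mean speed per epoch
#' defines the locomotor state: immobile (< 5 cm/s), moving (> 20 cm/s),
#' intermediate otherwise (labelled but excluded from state contrasts).
#'
#' @param trace prefiltered single-channel trace
#' @param speed speed trace on the same time base, cm/s
#' @param fs sampling rate, Hz
#' @param profile a [species_profile()]
#' @param epoch_len_s epoch length, s
#' @return data frame: `start` (s), `mean_speed`, `state`, `valid`, plus a
#'   list-column `samples`
#' @export
epoch_signal <- function(trace, speed, fs, profile, epoch_len_s = 1) {
  len <- round(epoch_len_s * fs)
  n_ep <- floor(length(trace) / len)
  stopifnot(length(speed) >= n_ep * len)
  res <- data.frame(start = (seq_len(n_ep) - 1) * epoch_len_s,
                    mean_speed = NA_real_, state = NA_character_,
                    valid = FALSE)
  samples <- vector("list", n_ep)
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1) * len + 1):(i * len)
    x <- trace[idx]
    v <- speed[idx]
    res$mean_speed[i] <- mean(v, na.rm = TRUE)
    res$state[i] <- if (is.na(res$mean_speed[i])) NA_character_
      else if (res$mean_speed[i] < profile$immobile_threshold) "immobile"
      else if (res$mean_speed[i] > profile$moving_epoch_threshold) "moving"
      else "intermediate"
    res$valid[i] <- !anyNA(x) && !anyNA(v)
    samples[[i]] <- x
  }
  res$samples <- samples
  res
}

#' Biased autocorrelogram of an epoch
#'
#' Divide-by-N (biased) autocorrelation computed by FFT, normalised to 1
#' at lag zero, over lags 0..`max_lag` samples. Data epochs and the
#' sinusoid bank use identical settings so the triangular taper cancels in
#' the peak-range normalisation.
#'
#' @param x epoch samples (no NAs); demeaned internally
#' @param max_lag maximum lag in samples (default length(x) - 1)
#' @return numeric vector of length `max_lag + 1`; value 1 at lag 0
#' @export
autocorrelogram <- function(x, max_lag = length(x) - 1) {
  if (anyNA(x)) stop("epoch contains masked samples", call. = FALSE)
  x <- x - mean(x)
  s0 <- sum(x^2)
  if (s0 == 0) stop("zero-variance epoch", call. = FALSE)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n - 1))
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1)] / nfft
  r / r[1]
}

#' Reference autocorrelogram bank for grid sinusoids
#'
#' One-second sinusoids at every grid frequency (`lo:hi` in `step`
#' increments), autocorrelated with the same estimator and lag grid as the
#' data epochs.
#'
#' @param profile a [species_profile()] (grid from `profile$sine_grid`)
#' @param fs sampling rate, Hz
#' @param epoch_len_s epoch length, s
#' @return object of class `tq_sine_bank`: list with `freq` and matrix
#'   `acg` (frequency x lag)
#' @export
sine_bank <- function(profile, fs, epoch_len_s = 1) {
  g <- profile$sine_grid
  freqs <- seq(g[1], g[2], by = g[3])
  n <- round(epoch_len_s * fs)
  tt <- (seq_len(n) - 1) / fs
  acg <- t(vapply(freqs,
                  function(f) autocorrelogram(sin(2 * pi * f * tt)),
                  numeric(n)))
  structure(list(freq = freqs, acg = acg, fs = fs, n = n),
            class = "tq_sine_bank")
}

#' Match an epoch autocorrelogram to the sinusoid bank
#'
#' Returns the grid frequency minimising the Euclidean distance between
#' the epoch autocorrelogram and each reference, normalised by the
#' Euclidean norm of the reference. Ties go to the lower frequency.
#'
#' @param acg epoch autocorrelogram (same lag grid as the bank)
#' @param bank a [sine_bank()]
#' @param normalise divide each distance by the reference norm (the
#'   default); `FALSE` gives the raw-distance variant
#' @return list: `frequency` (Hz), `reference` (matched autocorrelogram),
#'   `distance`
#' @export
match_sine <- function(acg, bank, normalise = TRUE) {
  stopifnot(inherits(bank, "tq_sine_bank"),
            length(acg) == ncol(bank$acg))
  diffs <- bank$acg - matrix(acg, nrow(bank$acg), length(acg), byrow = TRUE)
  ed <- sqrt(rowSums(diffs^2))
  if (normalise) ed <- ed / sqrt(rowSums(bank$acg^2))
  i <- which.min(ed)                      # which.min takes the first = lowest f
  list(frequency = bank$freq[i], reference = bank$acg[i, ],
       distance = ed[i])
}

## lag indices (1-based, lag 0 = index 1) of the first peak and its two
## flanking troughs of a reference sinusoid autocorrelogram
ref_extrema_lags <- function(ref) {
  d <- diff(ref)
  up <- which(d[-1] > 0 & d[-length(d)] <= 0) + 1L    # local minima
  dn <- which(d[-1] < 0 & d[-length(d)] >= 0) + 1L    # local maxima
  if (length(dn) == 0 || length(up) == 0) return(NULL)
  trough1 <- up[1]
  peak1 <- dn[dn > trough1][1]
  trough2 <- up[up > peak1][1]
  if (is.na(peak1) || is.na(trough2)) return(NULL)
  c(trough1 = trough1, peak = peak1, trough2 = trough2)
}

#' Normalised first-peak range of an epoch autocorrelogram
#'
#' The first peak and flanking troughs are located on the matched
#' sinusoid's autocorrelogram; the data extremum is measured within a
#' quarter period of each reference lag; the raw range (peak value minus
#' the mean of the two trough values) is divided by the identically
#' measured range of the reference. Values are not clipped. Epochs whose
#' matched frequency puts the second trough beyond the lag grid are
#' undefined (NA).
#'
#' @param acg epoch autocorrelogram
#' @param matched result of [match_sine()]
#' @param fs sampling rate, Hz
#' @return scalar peak range (dimensionless), or NA when undefined
#' @export
peak_range <- function(acg, matched, fs) {
  ref <- matched$reference
  lags <- ref_extrema_lags(ref)
  if (is.null(lags)) return(NA_real_)
  quarter <- round(fs / matched$frequency / 4)
  if (lags["trough2"] + quarter > length(acg)) return(NA_real_)
  win <- function(i) max(1L, i - quarter):min(length(acg), i + quarter)
  measure <- function(v) {
    pk <- max(v[win(lags["peak"])])
    tr <- (min(v[win(lags["trough1"])]) + min(v[win(lags["trough2"])])) / 2
    pk - tr
  }
  measure(acg) / measure(ref)
}

#' Run the epoch statistic over a session channel
#'
#' Composes prefilter, epoching, autocorrelation, sinusoid matching,
#' peak-range measurement and locomotor-state labelling into one record
#' per valid epoch.
#'
#' @param session a `tq_session` with a speed trace
#' @param channel channel index
#' @param bank optional precomputed [sine_bank()]
#' @param epoch_len_s epoch length, s
#' @return data frame of epoch records: `start`, `channel`, `mean_speed`,
#'   `state`, `est_frequency`, `peak_range`, `valid`
#' @export
epoch_pipeline <- function(session, channel, bank = NULL, epoch_len_s = 1) {
  stopifnot(inherits(session, "tq_session"), !is.null(session$speed))
  profile <- session$species_profile
  fs <- session$recording$fs
  if (is.null(bank)) bank <- sine_bank(profile, fs, epoch_len_s)
  x <- session$recording$samples[channel, ]
  x[!session$recording$valid_mask[channel, ]] <- NA
  filt <- prefilter_for_acg(x, profile, fs)
  ep <- epoch_signal(filt, session$speed, fs, profile, epoch_len_s)
  ep$est_frequency <- NA_real_
  ep$peak_range <- NA_real_
  for (i in which(ep$valid)) {
    xs <- ep$samples[[i]]
    if (stats::sd(xs) == 0) { ep$valid[i] <- FALSE; next }
    acg <- autocorrelogram(xs)
    m <- match_sine(acg, bank)
    ep$est_frequency[i] <- m$frequency
    ep$peak_range[i] <- peak_range(acg, m, fs)
  }
  ep$channel <- channel
  ep$samples <- NULL
  ep[, c("start", "channel", "mean_speed", "state", "est_frequency",
         "peak_range", "valid")]
}
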