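## Peak-trough estimation of instantaneous theta properties.

#' Band-pass filter a trace at the species theta band
#'
#' Hamming-windowed sinc FIR at the species band (rat 4-14 Hz, order
#' 500 ms; ferret 2-8 Hz, order 1000 ms), executed zero-lag by group-delay
#' compensation. Samples within half the order of either edge are NA.
#'
#' @param signal single-channel trace (NA where masked)
#' @param profile a [species_profile()]
#' @param fs sampling rate, Hz
#' @return filtered trace, same length; NA at edges and around masked
#'   samples
#' @export
bandpass_theta <- function(signal, profile, fs) {
  b <- fir_bandpass(profile$theta_band, profile$theta_fir_order_s, fs)
  if (length(signal) <= length(b) - 1)
    stop("signal shorter than the filter order", call. = FALSE)
  nas <- is.na(signal)
  x <- signal
  x[nas] <- 0
  y <- fir_zero_lag(b, x)
  if (any(nas)) {
    ## invalidate outputs whose filter window touched a masked sample
    gd <- (length(b) - 1L) %/% 2L
    y[dilate_runs(nas, pad = gd)] <- NA
  }
  y
}

#' Detect alternating peaks and troughs by voltage-range scanning
#'
#' Point-by-point scan of the filtered trace: a peak (trough) is confirmed
#' once the signal has fallen (risen) from the running extremum by more
#' than `threshold_factor` x the session-level median absolute amplitude.
#' Confirmed extrema strictly alternate; sub-threshold wiggles are
#' ignored. Ties are broken towards the earlier sample. Masked (NA)
#' samples split the trace: extrema are never detected across a gap.
#'
#' @param filtered band-passed trace (NA allowed)
#' @param threshold_factor scan threshold as a fraction of the median
#'   absolute amplitude (default 0.25)
#' @param median_amp optional precomputed session median absolute
#'   amplitude
#' @return data frame: `index` (sample), `value` (uV), `kind`
#'   (`"peak"`/`"trough"`), strictly alternating within each unmasked
#'   segment
#' @export
detect_extrema <- function(filtered, threshold_factor = 0.25,
                           median_amp = NULL) {
  if (is.null(median_amp))
    median_amp <- stats::median(abs(filtered), na.rm = TRUE)
  thr <- threshold_factor * median_amp
  if (!is.finite(thr) || thr <= 0)
    return(data.frame(index = integer(0), value = numeric(0),
                      kind = character(0)))
  segs <- unmasked_segments(!is.na(filtered))
  out <- list()
  for (s in seq_len(nrow(segs))) {
    idx <- segs$start[s]:segs$end[s]
    ext <- scan_extrema(filtered[idx], thr)
    if (nrow(ext) > 0) {
      ext$index <- ext$index + segs$start[s] - 1L
      out[[length(out) + 1]] <- ext
    }
  }
  if (length(out) == 0)
    return(data.frame(index = integer(0), value = numeric(0),
                      kind = character(0)))
  do.call(rbind, out)
}

## start/end indices of TRUE runs
unmasked_segments <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

## Voltage-range scan over one contiguous segment. Operates on the
## candidate turning points of the trace (its discrete local extrema plus
## the endpoints), which is exactly where the point-by-point scan can turn.
scan_extrema <- function(x, thr) {
  n <- length(x)
  empty <- data.frame(index = integer(0), value = numeric(0),
                      kind = character(0))
  if (n < 3) return(empty)
  d <- diff(x)
  ## candidate turning points; ties broken toward the earlier sample by
  ## treating flat steps as continuation
  sgn <- sign(d)
  sgn[sgn == 0] <- NA
  sgn <- fill_forward(sgn)
  turn <- which(diff(sgn) != 0 & !is.na(diff(sgn))) + 1L
  cand <- unique(c(1L, turn, n))
  ## endpoints are tracked but never emitted: a running extremum at a
  ## segment boundary is not a confirmed turning point
  emittable <- cand %in% turn
  cv <- x[cand]
  idx <- integer(0); val <- numeric(0); kind <- character(0)
  mode <- 0L                       # 0 unknown, 1 seeking peak, -1 seeking trough
  emit <- function(i, v, what, ok) {
    if (ok) {
      idx <<- c(idx, i); val <<- c(val, v); kind <<- c(kind, what)
    }
  }
  run_i <- cand[1]; run_v <- cv[1]; run_ok <- emittable[1]
  run_min_i <- cand[1]; run_min_v <- cv[1]; run_min_ok <- emittable[1]
  for (k in seq_along(cand)) {
    v <- cv[k]; i <- cand[k]; ok <- emittable[k]
    if (mode == 0L) {
      ## seed: wait until the range since the start exceeds thr either way
      if (v > run_v) { run_v <- v; run_i <- i; run_ok <- ok }
      if (v < run_min_v) { run_min_v <- v; run_min_i <- i; run_min_ok <- ok }
      if (run_v - v > thr) {       # fell from max: that max was a peak
        emit(run_i, run_v, "peak", run_ok)
        mode <- -1L; run_v <- v; run_i <- i; run_ok <- ok
      } else if (v - run_min_v > thr) {
        emit(run_min_i, run_min_v, "trough", run_min_ok)
        mode <- 1L; run_v <- v; run_i <- i; run_ok <- ok
      }
    } else if (mode == 1L) {       # seeking peak: track running max
      if (v > run_v) { run_v <- v; run_i <- i; run_ok <- ok }
      else if (run_v - v > thr) {
        emit(run_i, run_v, "peak", run_ok)
        mode <- -1L; run_v <- v; run_i <- i; run_ok <- ok
      }
    } else {                       # seeking trough: track running min
      if (v < run_v) { run_v <- v; run_i <- i; run_ok <- ok }
      else if (v - run_v > thr) {
        emit(run_i, run_v, "trough", run_ok)
        mode <- 1L; run_v <- v; run_i <- i; run_ok <- ok
      }
    }
  }
  if (length(idx) == 0) return(empty)
  data.frame(index = idx, value = val, kind = kind)
}

fill_forward <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x
  out[idx > 0] <- x[idx[idx > 0]]
  out
}

#' Instantaneous theta frequency, amplitude, power and phase
#'
#' Frequency is the mean of the peak-interval frequency (inverse time
#' between successive peaks) and the trough-interval frequency, assigned
#' at interval midpoints and linearly interpolated per sample. Amplitude
#' is the mean of |peak| and |trough| values, held constant within each
#' half-cycle; power is amplitude squared. Phase sets peaks to 0 degrees
#' and troughs to 180 and interpolates linearly, so phase is exactly 0 at
#' peak samples and circularly nondecreasing between extrema. Samples
#' outside the first/last extremum are NA.
#'
#' @param extrema data frame from [detect_extrema()]
#' @param n_samples output length
#' @param fs sampling rate, Hz
#' @return data frame: `frequency` (Hz), `amplitude` (uV), `power`
#'   (uV^2), `phase` (degrees in [0, 360))
#' @export
instantaneous_theta <- function(extrema, n_samples, fs) {
  frequency <- rep(NA_real_, n_samples)
  amplitude <- rep(NA_real_, n_samples)
  phase <- rep(NA_real_, n_samples)
  empty <- data.frame(frequency = frequency, amplitude = amplitude,
                      power = NA_real_, phase = phase)
  pk <- extrema[extrema$kind == "peak", ]
  tr <- extrema[extrema$kind == "trough", ]
  if (nrow(pk) < 2 || nrow(tr) < 2) {
    warning("insufficient extrema for instantaneous estimates")
    return(empty)
  }
  e <- extrema[order(extrema$index), ]
  ## maximal alternating stretches (masking gaps break alternation)
  brk <- which(e$kind[-1] == e$kind[-nrow(e)])
  stretch_start <- c(1L, brk + 1L)
  stretch_end <- c(brk, nrow(e))
  for (s in seq_along(stretch_start)) {
    es <- e[stretch_start[s]:stretch_end[s], ]
    if (nrow(es) < 3) next
    pk <- es[es$kind == "peak", ]
    tr <- es[es$kind == "trough", ]
    freq_events <- function(q) {
      if (nrow(q) < 2) return(NULL)
      data.frame(mid = (q$index[-1] + q$index[-nrow(q)]) / 2,
                 f = fs / diff(q$index))
    }
    ev <- rbind(freq_events(pk), freq_events(tr))
    if (is.null(ev) || nrow(ev) < 1) next
    ev <- ev[order(ev$mid), ]
    span <- es$index[1]:es$index[nrow(es)]
    frequency[span] <- if (nrow(ev) == 1) ev$f else
      stats::approx(ev$mid, ev$f, xout = span, rule = 2)$y
    ## amplitude held constant within each half-cycle
    half_amp <- (abs(es$value[-nrow(es)]) + abs(es$value[-1])) / 2
    amplitude[span] <- c(rep(half_amp, diff(es$index)),
                         half_amp[length(half_amp)])
    ## unwrapped phase: 180 deg per half-cycle, peaks anchored at 0 mod 360
    ph_unwrap <- (if (es$kind[1] == "peak") 0 else 180) +
      (seq_len(nrow(es)) - 1) * 180
    phase[span] <- stats::approx(es$index, ph_unwrap, xout = span)$y %% 360
  }
  data.frame(frequency = frequency, amplitude = amplitude,
             power = amplitude^2, phase = phase)
}
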