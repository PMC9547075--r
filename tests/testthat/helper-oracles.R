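# Independent oracles kept deliberately naive: direct time-domain sums and
# loop-based measurements, sharing no code path with the package.

# O(N^2) biased autocorrelation, normalised at lag 0
acg_oracle <- function(x, max_lag = length(x) - 1) {
  x <- x - mean(x)
  n <- length(x)
  r <- sapply(0:max_lag, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n)
  r / r[1]
}

# Clean-room peak range: locate the reference's first trough/peak/trough by
# explicit scanning, then measure data extrema in quarter-period windows.
peak_range_oracle <- function(acg, ref, freq, fs) {
  n <- length(ref)
  first_min_after <- function(v, from) {
    for (i in (from + 1):(n - 1)) {
      if (v[i] < v[i - 1] && v[i] <= v[i + 1]) return(i)
    }
    NA_integer_
  }
  first_max_after <- function(v, from) {
    for (i in (from + 1):(n - 1)) {
      if (v[i] > v[i - 1] && v[i] >= v[i + 1]) return(i)
    }
    NA_integer_
  }
  t1 <- first_min_after(ref, 1)
  pk <- first_max_after(ref, t1)
  t2 <- first_min_after(ref, pk)
  if (is.na(t1) || is.na(pk) || is.na(t2)) return(NA_real_)
  q <- round(fs / freq / 4)
  if (t2 + q > n) return(NA_real_)
  rng <- function(v) {
    w <- function(i) v[max(1, i - q):min(n, i + q)]
    max(w(pk)) - (min(w(t1)) + min(w(t2))) / 2
  }
  rng(acg) / rng(ref)
}

# FFT analytic-signal phase/frequency oracle (independent of the
# peak-trough estimator path)
hilbert_oracle <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  a <- fft(X * h, inverse = TRUE) / n
  ph <- Arg(a)
  unph <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi)) -
    2 * pi * cumsum(c(0, diff(ph) > pi))
  freq <- c(NA, diff(unph)) * fs / (2 * pi)
  list(phase_deg = (ph * 180 / pi) %% 360, frequency = freq,
       amplitude = Mod(a))
}

# brute-force alternating-extrema count for a trace with threshold
count_alternating_extrema_oracle <- function(x, thr) {
  # all strict local extrema, then greedy alternation with range check
  n <- length(x)
  loc <- integer(0); kind <- character(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) { loc <- c(loc, i); kind <- c(kind, "peak") }
    if (x[i] < x[i - 1] && x[i] <= x[i + 1]) { loc <- c(loc, i); kind <- c(kind, "trough") }
  }
  kept_kind <- character(0); kept_val <- numeric(0)
  for (j in seq_along(loc)) {
    v <- x[loc[j]]
    if (length(kept_kind) == 0) { kept_kind <- kind[j]; kept_val <- v; next }
    last <- length(kept_kind)
    if (kind[j] == kept_kind[last]) {
      better <- (kind[j] == "peak" && v > kept_val[last]) ||
        (kind[j] == "trough" && v < kept_val[last])
      if (better) kept_val[last] <- v
    } else if (abs(v - kept_val[last]) > thr) {
      kept_kind <- c(kept_kind, kind[j]); kept_val <- c(kept_val, v)
    }
  }
  table(factor(kept_kind, levels = c("peak", "trough")))
}
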