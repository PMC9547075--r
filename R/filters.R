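## IIR/FIR filter design and zero-phase execution.
##
## High-order Chebyshev type II designs (notably the 14th-order 50 Hz
## band-stop at fs = 1 kHz) are numerically unstable when expressed as a
## single transfer function, so designs are carried through in zero-pole-gain
## form and executed as a cascade of second-order sections (biquads).

#' Chebyshev type II analog lowpass prototype (zero-pole-gain)
#'
#' @param n filter order
#' @param rs stopband attenuation, dB
#' @return list with complex `z` (zeros), `p` (poles), numeric `k` (gain);
#'   stopband edge normalised to 1 rad/s
#' @keywords internal
#' @noRd
cheb2_prototype <- function(n, rs) {
  de <- 1 / sqrt(10^(0.1 * rs) - 1)
  mu <- asinh(1 / de) / n
  m_p <- seq(-n + 1, n - 1, by = 2)
  p <- -exp(1i * pi * m_p / (2 * n))
  p <- complex(real = sinh(mu) * Re(p), imaginary = cosh(mu) * Im(p))
  p <- 1 / p
  m_z <- if (n %% 2 == 1) c(seq(-n + 1, -2, by = 2), seq(2, n - 1, by = 2)) else m_p
  z <- Conj(1i / sin(m_z * pi / (2 * n)))
  k <- Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = k)
}

## Lowpass prototype -> highpass at angular frequency wo (rad/s)
lp2hp_zpk <- function(zpk, wo) {
  degree <- length(zpk$p) - length(zpk$z)
  z <- wo / zpk$z
  p <- wo / zpk$p
  z <- c(z, rep(0 + 0i, degree))
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

## Lowpass prototype -> band-stop, centre wo, width bw (rad/s)
lp2bs_zpk <- function(zpk, wo, bw) {
  degree <- length(zpk$p) - length(zpk$z)
  z_inv <- (bw / 2) / zpk$z
  p_inv <- (bw / 2) / zpk$p
  z <- c(z_inv + sqrt(z_inv^2 - wo^2), z_inv - sqrt(z_inv^2 - wo^2))
  p <- c(p_inv + sqrt(p_inv^2 - wo^2), p_inv - sqrt(p_inv^2 - wo^2))
  z <- c(z, rep(1i * wo, degree), rep(-1i * wo, degree))
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = z, p = p, k = k)
}

## Bilinear transform of an analog zpk design (fs in Hz). Analog critical
## frequencies must already be prewarped with `prewarp()`.
bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  degree <- length(zpk$p) - length(zpk$z)
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  zd <- c(zd, rep(-1 + 0i, degree))
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = zd, p = pd, k = kd)
}

prewarp <- function(f_hz, fs) 2 * fs * tan(pi * f_hz / fs)

## Pair conjugate zeros/poles of a digital zpk into second-order sections.
## Poles are consumed closest-to-unit-circle first; each pole pair takes the
## remaining zero pair nearest to it. Gain is folded into the first section.
zpk2sos <- function(zpk, tol = 1e-8) {
  take_pairs <- function(v) {
    up <- v[Im(v) > tol]
    re <- Re(v[abs(Im(v)) <= tol])
    if (length(re) %% 2 != 0)
      stop("unpaired real root in zpk2sos; unsupported design")
    re <- sort(re)
    pairs <- lapply(up, function(x) c(x, Conj(x)))
    if (length(re) > 0)
      pairs <- c(pairs, lapply(seq(1, length(re), by = 2),
                               function(i) as.complex(re[c(i, i + 1)])))
    pairs
  }
  pp <- take_pairs(zpk$p)
  zp <- take_pairs(zpk$z)
  if (length(pp) != length(zp))
    stop("zpk2sos requires equal numbers of pole and zero pairs")
  ord <- order(-abs(vapply(pp, function(q) q[1], complex(1))))
  pp <- pp[ord]
  sos <- vector("list", length(pp))
  used <- rep(FALSE, length(zp))
  for (i in seq_along(pp)) {
    d <- vapply(zp, function(q) abs(q[1] - pp[[i]][1]), numeric(1))
    d[used] <- Inf
    j <- which.min(d)
    used[j] <- TRUE
    b <- Re(c(1, -(zp[[j]][1] + zp[[j]][2]), zp[[j]][1] * zp[[j]][2]))
    a <- Re(c(1, -(pp[[i]][1] + pp[[i]][2]), pp[[i]][1] * pp[[i]][2]))
    sos[[i]] <- rbind(b, a)
  }
  sos[[1]][1, ] <- sos[[1]][1, ] * zpk$k
  sos
}

#' Design a digital Chebyshev type II filter as second-order sections
#'
#' @param n prototype order (final order is `n` for `"high"`, `2n` for
#'   `"stop"`)
#' @param rs stopband attenuation in dB
#' @param f_hz critical frequency (scalar for `"high"`: stopband edge;
#'   length-2 for `"stop"`: stopband edges)
#' @param fs sampling rate, Hz
#' @param type `"high"` or `"stop"`
#' @return object of class `tq_sos`: list of 2x3 (b, a) biquad matrices
#' @keywords internal
#' @noRd
design_cheby2_sos <- function(n, rs, f_hz, fs, type = c("high", "stop")) {
  type <- match.arg(type)
  proto <- cheb2_prototype(n, rs)
  if (type == "high") {
    wo <- prewarp(f_hz, fs)
    zpk <- lp2hp_zpk(proto, wo)
  } else {
    w <- prewarp(f_hz, fs)
    wo <- sqrt(w[1] * w[2])
    zpk <- lp2bs_zpk(proto, wo, diff(w))
  }
  sos <- zpk2sos(bilinear_zpk(zpk, fs))
  structure(sos, class = "tq_sos", fs = fs)
}

#' Chebyshev type II high-pass specified by its passband edge
#'
#' `design_cheby2_sos()` takes the stopband edge; published filter specs
#' often state the passband edge instead. The stopband edge is solved by
#' bisection so the single-pass response at `fp_hz` is `ripple_db` down.
#'
#' @param n order; @param rs stopband attenuation dB; @param fp_hz passband
#'   edge Hz; @param fs sampling rate Hz; @param ripple_db allowed loss at
#'   the passband edge (default 1 dB)
#' @return `tq_sos` cascade
#' @keywords internal
#' @noRd
design_cheby2_hp_passband <- function(n, rs, fp_hz, fs, ripple_db = 1) {
  att_at_fp <- function(ws) {
    s <- design_cheby2_sos(n, rs, ws, fs, "high")
    -20 * log10(Mod(sos_response(s, fp_hz, fs)))
  }
  lo <- fp_hz / 50
  hi <- fp_hz * 0.999
  ws <- stats::uniroot(function(w) att_at_fp(w) - ripple_db,
                       lower = lo, upper = hi, tol = 1e-6)$root
  design_cheby2_sos(n, rs, ws, fs, "high")
}

#' Frequency response magnitude of an SOS cascade
#'
#' @param sos `tq_sos` object
#' @param f_hz frequencies to evaluate, Hz
#' @param fs sampling rate, Hz
#' @return complex response at each frequency
#' @keywords internal
#' @noRd
sos_response <- function(sos, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  h <- rep(1 + 0i, length(w))
  for (sec in sos) {
    zm1 <- exp(-1i * w)
    num <- sec[1, 1] + sec[1, 2] * zm1 + sec[1, 3] * zm1^2
    den <- sec[2, 1] + sec[2, 2] * zm1 + sec[2, 3] * zm1^2
    h <- h * num / den
  }
  h
}

## Zero-phase (forward-backward) execution of an SOS cascade.
sos_filtfilt <- function(sos, x) {
  y <- x
  for (sec in sos)
    y <- signal::filtfilt(signal::Arma(b = sec[1, ], a = sec[2, ]), y)
  y
}

#' Zero-lag FIR filtering with group-delay compensation
#'
#' Applies a linear-phase FIR filter and shifts the output by the group
#' delay (order/2 samples) so peaks line up with the input. The first and
#' last order/2 samples, where the filter window is incomplete, are NA.
#'
#' @param b FIR coefficients (odd length; even order)
#' @param x signal
#' @return filtered signal, same length, edges NA
#' @keywords internal
#' @noRd
fir_zero_lag <- function(b, x) {
  n <- length(x)
  order <- length(b) - 1L
  if (order %% 2L != 0L) stop("FIR order must be even for exact compensation")
  if (n <= order) stop("signal shorter than filter order")
  gd <- order %/% 2L
  ## linear convolution by FFT (n log n)
  nfft <- 2^ceiling(log2(n + order))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(b, numeric(nfft - length(b)))),
                     inverse = TRUE)) / nfft
  out <- y[(gd + 1L):(gd + n)]
  out[seq_len(gd)] <- NA_real_
  out[(n - gd + 1L):n] <- NA_real_
  out
}

#' Linear-phase FIR band-pass by frequency sampling (Hamming window)
#'
#' The stated band is treated as the passband (unit gain throughout), with
#' raised-cosine transitions of the window-limited width (~3.3/order * fs)
#' outside it. Order is `round(order_s * fs)`, forced even so the group
#' delay is an integer number of samples.
#'
#' @param band length-2 numeric, Hz (passband edges)
#' @param order_s filter order expressed as a duration, s
#' @param fs sampling rate, Hz
#' @return coefficient vector of length order + 1
#' @keywords internal
#' @noRd
fir_bandpass <- function(band, order_s, fs) {
  order <- round(order_s * fs)
  if (order %% 2 != 0) order <- order + 1
  tw <- 2.5 / order * fs
  nyq <- fs / 2
  lo0 <- max(band[1] * 0.1, band[1] - tw)
  hi1 <- min(nyq * 0.99, band[2] + tw)
  ## piecewise-linear approximation of raised-cosine transitions
  ramp <- function(a, b) {
    u <- seq(0.1, 0.9, by = 0.2)
    list(f = a + u * (b - a), m = (1 - cos(pi * u)) / 2)
  }
  up <- ramp(lo0, band[1])
  dn <- ramp(band[2], hi1)
  f <- c(0, lo0, up$f, band[1], band[2], dn$f, hi1, nyq) / nyq
  m <- c(0, 0, up$m, 1, 1, rev(dn$m), 0, 0)
  signal::fir2(order, f, m)
}

#' Analytic-signal envelope and phase via FFT
#'
#' @param x real signal (no NAs)
#' @return complex analytic signal
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
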