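#' Species-specific analysis constants
#'
#' Bundles every species-dependent constant used by the pipeline: theta
#' filter band and FIR order, the high-pass / notch prefilter specs for the
#' autocorrelogram stage, the matched-sinusoid frequency grid, channel
#' exclusion thresholds, and the speed cutoffs that define locomotor states.
#'
#' Rat theta is filtered at 4-14 Hz with a 500 ms-order FIR; ferret theta at
#' 2-8 Hz with a 1000 ms-order FIR, reflecting the lower ferret theta
#' frequency. The autocorrelogram prefilter is a Chebyshev type II high-pass
#' (rat: 6th order, 80 dB, 2 Hz passband edge; ferret: 4th order, 80 dB,
#' 1 Hz) plus a 14th-order Chebyshev type II 50 Hz band-stop (60 dB,
#' stopband 49-51 Hz). The sinusoid grid runs 4-14 Hz (rat) or 2-14 Hz
#' (ferret) in 0.1 Hz steps.
#'
#' Speed cutoffs: epochs with mean speed below `immobile_threshold`
#' (5 cm/s) are immobile, above `moving_epoch_threshold` (20 cm/s) moving;
#' intermediate epochs are labelled but excluded from state contrasts.
#' `move_threshold` (5 cm/s) is the per-sample threshold gating rat theta,
#' and `locomotion_threshold` (10 cm/s) selects locomotion data for PSDs,
#' depth profiles and speed regressions.
#'
#' @param name `"rat"` or `"ferret"`
#' @return object of class `tq_species_profile` (a named list)
#' @examples
#' p <- species_profile("rat")
#' p$theta_band
#' @export
species_profile <- function(name = c("rat", "ferret")) {
  name <- match.arg(name)
  common <- list(
    name = name,
    notch_spec = list(order = 14, rs_db = 60, stopband_hz = c(49, 51)),
    scratch_band = c(6, 13),
    scratch_fir_order_s = 0.5,
    scratch_threshold_factor = 10,
    mains_hz = 50,
    mains_margin_db = 0,
    move_threshold = 5,
    immobile_threshold = 5,
    moving_epoch_threshold = 20,
    locomotion_threshold = 10,
    psd_nfft = 4096
  )
  sp <- if (name == "rat") {
    list(
      theta_band = c(4, 14),
      theta_fir_order_s = 0.5,
      hp_filter = list(order = 6, rs_db = 80, passband_hz = 2),
      sine_grid = c(4, 14, 0.1),
      theta_power_exclusion_db = 4,
      psd_theta_band = c(6, 13)
    )
  } else {
    list(
      theta_band = c(2, 8),
      theta_fir_order_s = 1.0,
      hp_filter = list(order = 4, rs_db = 80, passband_hz = 1),
      sine_grid = c(2, 14, 0.1),
      theta_power_exclusion_db = 2,
      psd_theta_band = c(4, 7)
    )
  }
  structure(c(common, sp), class = "tq_species_profile")
}

#' @export
print.tq_species_profile <- function(x, ...) {
  cat("Species profile:", x$name, "\n")
  cat("  theta band:", paste(x$theta_band, collapse = "-"), "Hz, FIR order",
      x$theta_fir_order_s, "s\n")
  cat("  sine grid:", paste(x$sine_grid, collapse = ":"), "Hz\n")
  cat("  speed cutoffs (immobile/moving/locomotion):",
      x$immobile_threshold, "/", x$moving_epoch_threshold, "/",
      x$locomotion_threshold, "cm/s\n")
  invisible(x)
}
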