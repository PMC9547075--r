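---
title: "Quantifying hippocampal theta with matched-sinusoid autocorrelograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal theta with matched-sinusoid autocorrelograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetaquant)
```

## The problem

Hippocampal theta (4–12 Hz in rodents, lower in carnivores) is the
dominant oscillation of the hippocampal local field potential (LFP)
during locomotion. Comparing theta *across species* is hard for two
reasons. First, the classic rodent state marker — the delta/theta power
ratio — fails when a species' theta band overlaps delta. Second, raw
band power confounds oscillation *regularity* with amplitude: filtered
large irregular activity (LIA) still carries band power even when no
rhythm is present.

This package implements an analysis chain built around a statistic that
measures rhythmicity itself: the **normalised autocorrelogram peak
range**. The LFP is segmented into 1 s epochs; each epoch's biased,
lag-0-normalised autocorrelogram is compared (normalised Euclidean
distance) against a bank of autocorrelograms of pure sinusoids on a
0.1 Hz grid (4–14 Hz for rat, 2–14 Hz for ferret). The best-matching
sinusoid gives the epoch's frequency estimate, and the range of the
first autocorrelogram peak (peak value minus the mean of the two
flanking troughs, measured within a quarter period of the matched
reference's extremum lags) is divided by the identical measurement on
the matched reference. Periodic in-band signals score ≈ 1; white noise
scores ≈ 0 (mean ≈ 0.08 over seeded noise epochs). Because data and
reference use the same estimator and lag grid, the triangular bias
taper cancels in the ratio.

## The pipeline

1. **Cleaning** (`clean_session()`): channels are excluded when the
   theta-band PSD peak (Welch, Hanning window, nfft 4096, 50% overlap)
   does not rise above the interpolated 1/f background by the species
   threshold (4 dB rat, 2 dB ferret) or when 50 Hz power exceeds the
   theta peak. Amplitude artifacts are masked where the cross-channel
   mean absolute amplitude exceeds 10 × the mode of its distribution
   (Freedman–Diaconis histogram mode); zeros and rail saturation get
   their own labels. For rat sessions, scratching and high-voltage
   spike-wave epochs are removed by thresholding the median 6–13 Hz
   Hilbert power of the cortical channels at 10 × its mode; supra-
   threshold sections are masked on all channels.
2. **Head tracking** (`clean_tracking()`, `compute_speed()`): LED
   reflections are removed by per-frame jump (> 50 px) and LED
   separation (outside 30–50 px) constraints; gaps under 660 ms are
   linearly interpolated, positions median-filtered (width 5). Speed is
   the frame-to-frame head displacement (mean of the two LEDs) scaled
   by the rig's px/cm and aligned to the LFP time base.
3. **Peak-trough theta estimation** (`bandpass_theta()`,
   `detect_extrema()`, `instantaneous_theta()`): the theta-filtered
   trace (rat 4–14 Hz FIR of order 500 ms; ferret 2–8 Hz, 1000 ms;
   zero-lag by group-delay compensation) is scanned point by point for
   alternating extrema whose excursion exceeds 0.25 × the session
   median absolute amplitude. Instantaneous frequency is the mean of
   the peak-interval and trough-interval frequencies (interval
   midpoints, linearly interpolated per sample); amplitude is the mean
   of |peak| and |trough| per half-cycle; phase anchors peaks at 0° and
   troughs at 180°.
4. **Epoch statistic** (`epoch_pipeline()`): high-pass (Chebyshev II;
   rat 6th order/80 dB/2 Hz passband edge, ferret 4th order/1 Hz) and
   50 Hz notch (14th-order Chebyshev II band-stop, 60 dB, stopband
   49–51 Hz), both zero-phase; 1 s epochs; autocorrelogram; matched
   sinusoid; peak range; locomotor state from mean epoch speed
   (immobile < 5 cm/s, moving > 20 cm/s, intermediate labelled but
   excluded from contrasts).
5. **Laminar profiling** (`theta_depth_profile()`,
   `estimate_layers()`): per-channel median theta power and circular
   mean phase shift relative to the top channel, restricted to
   locomotion (speed > 10 cm/s, ≥ 60 s). The pyramidal layer is the
   power-minimising channel inside the zone where the phase gradient
   exceeds 20°/channel over at least two consecutive steps; stratum
   oriens sits 200 µm above, SR/SLM 400 µm below. Probes that never
   cross the layer fall back to the highest-power channel as SO.
6. **Trial epochs** (`extract_trial_epochs()`): Hold =
   [onset − 1.05, onset − 0.05) s; Run = the 1 s before the peripheral
   response; Reward = the first 1 s after the response with *every*
   speed sample below 5 cm/s.
7. **Mixed models** (`fit_lmm()`, `lmm_split_protocol()`,
   `tukey_contrasts()`): epoch peak range is modelled with nested
   random intercepts (lme4/lmerTest, REML, Satterthwaite p by default,
   Wald z optional, method always recorded). The registry `eq1`–`eq9`
   covers the full study design: state × species (+ per-species splits
   after a significant interaction), drug × state, and trial-epoch
   models with Run as reference and Tukey post-hoc contrasts (emmeans).

## Numerical choices

* **Filters.** High-order Chebyshev II designs are carried in
  zero-pole-gain form and executed as cascaded biquads; the 14th-order
  notch is numerically unstable as a single transfer function at
  1 kHz. The design is validated against an independent transfer-
  function implementation at orders where that is stable. FIR band-pass
  filters are frequency-sampling designs (Hamming window) whose stated
  band is the *passband* (unit gain throughout), with raised-cosine
  transitions outside it; the stated high-pass "passband edge" is
  honoured by solving for the stopband edge that leaves 1 dB at the
  edge.
* **Autocorrelograms** use the biased (divide-by-N) estimator over lags
  0–1000 ms, computed by FFT and tested to 1e-10 against an O(N²)
  time-domain sum. Distances to the sinusoid bank are normalised by
  each reference's Euclidean norm; ties take the lower frequency.
* **Extrema.** The voltage-range scan operates on the trace's candidate
  turning points; running extrema that sit on a segment boundary (the
  first/last sample, or the edge of a masked gap) are never emitted,
  because a boundary sample is not a confirmed turning point. Ties
  break toward the earlier sample. Masked samples split the trace;
  extrema never span a gap.
* **Speed regressions.** 250 ms epoch medians (speed and target paired
  over the same samples), epochs entirely above the 5 cm/s move
  threshold and with median speed > 10 cm/s, speeds above the 90th
  percentile excluded, 5 cm/s bins, ordinary least squares on the
  per-bin *medians of both variables*. Using bin midpoints as the
  abscissa instead biases slopes low by ~15% because edge bins are not
  centred on their midpoints near the 10 cm/s and 90th-percentile
  cuts; this was diagnosed by regressing the generator's true
  frequency through the identical procedure.
* **"Mode" of a continuous distribution** (artifact thresholds) is the
  centre of the fullest Freedman–Diaconis histogram bin — deterministic
  and scale-aware.
* **Degenerate inputs.** Zero-variance epochs error; epochs whose
  matched frequency puts the second autocorrelogram trough beyond the
  lag grid are flagged undefined, not extrapolated; insufficient
  extrema yield all-NA instantaneous estimates with a warning;
  single-level grouping factors are refused rather than silently
  simplified, and non-convergence is flagged in the output.

## The synthetic forward model

All tests run against `generate_session()`, which composes a
behavioural speed trace, a laminar LFP, and injected artifacts with
full ground truth.

* **Behaviour**: trials alternate inter-trial wandering (2–8 cm/s), an
  immobile Hold (speed ~0–2 cm/s; duration drawn from five values
  between 2.5 and 3.5 s), a run whose approach speed is drawn per trial
  from 16–32 cm/s and fluctuates ±15% on ~1 s knots (runs are
  quasi-stationary, not flat plateaus), deceleration, and an immobile
  reward dwell. Band-limited jitter (SD 1 cm/s, ~5 Hz) is added and
  clipped at zero. Mean moving speed (> 10 cm/s samples) lands in the
  20–35 cm/s range typical of both species on this task.
* **Theta**: per channel,
  `A_c(t)·g(t)·wave(φ(t) + δ_c; skew) + LIA_c(t)` with instantaneous
  frequency `f(t) = base + slope·v(t)` (defaults: rat 7.5 Hz + 0.026
  Hz/(cm/s); ferret 5.2 Hz + 0.010, minus a 1 Hz offset when immobile).
  `wave` is a cosine warped asymmetrically per cycle (rise fraction
  0.5 − 0.4·skew, default skew 0.4) so locomotion theta is sawtooth-like
  with a visible 2f harmonic; ferret immobility theta relaxes to a
  sinusoid. The rat gate `g(t)` switches theta on only above the 5 cm/s
  move threshold; ferret theta is always on; atropine mode forces the
  rat rule (immobility theta abolished, locomotion theta untouched).
  The laminar amplitude/phase profile emulates a 32-site probe: low
  cortical amplitudes, rising power through stratum oriens, a dip at
  the pyramidal layer where the ~180° phase shift begins, maximal power
  in SR/SLM; SR/SLM amplitudes gain ×1.3 inside reward windows
  (ferret), emulating reward-related enhancement of immobility theta.
* **LIA**: Gaussian 1/f^1.5 noise, low-pass shaped at 40 Hz, RMS 30 µV,
  synthesised at fs/4 and upsampled (the process is band-limited far
  below the decimated Nyquist).
* **Artifacts**: Poisson-timed broadband transients (≥ 10× typical
  amplitude, all channels), 8–12 Hz scratching bursts strongest on
  cortical channels, runs of exact zeros, and saturation at a ±2000 µV
  rail — each recorded in a ground-truth mask.

What the generator does *not* emulate: current-source geometry and
volume conduction, spiking and ripple content (beyond an optional test
burst), respiration coupling, non-stationary electrode drift, and
behaviourally realistic trial-to-trial variability beyond what is
parameterised. Passing tests therefore show that the chain recovers
what it is designed to measure under controlled statistical structure —
not that every constant is optimal for any particular recording rig.

## Known limitations

* Near rat theta onsets, extremum intervals bridge the LIA-to-theta
  transition and mix the band-filter's LIA pseudo-frequency into the
  first locomotion cycles; speed–frequency slopes estimated from
  rat-mode sessions are attenuated by a few percent relative to
  sessions with continuous theta. Parameter-recovery checks therefore
  use continuous-theta sessions; on real data the paper's approach of
  analysing the highest-power channel over long sessions makes this a
  second-order effect.
* Peak-trough timing is integer-sample; per-cycle frequency is
  quantised at ~f²/fs, which bounds chirp-tracking resolution
  (~0.07 Hz/cycle at 8 Hz, 1 kHz).
* The channel-exclusion thresholds are interpreted as theta-peak
  prominence above the interpolated 1/f background (in dB), keeping the
  rule calibration-free; absolute-dB readings depend on the recording
  system's scaling.
* With only one recording per subject, the nested random-intercept
  models are unidentifiable; the workflow scripts simulate two subjects
  per condition and split sessions into pseudo-sessions to keep all
  grouping levels estimable, and `fit_lmm()` refuses single-level
  groupings outright.

## Problem sizes used in the shipped analyses

The numbered scripts under `analysis/` and the acceptance checks use
240 s eight-channel sessions for state and trial contrasts, 150 s
sessions for slope recovery (10 seeds), 240 s 32-channel probes for
layer assignment (20 seeded probes, run-rich trial mix so ≥ 60 s of
locomotion is available), 500 simulated tables for the null-calibration
of the mixed model, and 200–500 seeded epochs for the metric
calibration and frequency-robustness checks. These sizes give stable
medians and rates while keeping the full chain quick to re-run.
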