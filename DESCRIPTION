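Package: thetaquant
Title: Autocorrelogram-Based Quantification of Hippocampal Theta Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for quantifying hippocampal theta oscillations
    in multichannel local field potential (LFP) recordings across species and
    locomotor states. Implements LFP artifact cleaning (amplitude transients,
    zeros/saturation, cortical scratching and high-voltage spike-wave
    removal), head-tracking cleanup and speed estimation, peak-trough
    estimation of instantaneous theta frequency/amplitude/phase, an
    autocorrelogram matched-sinusoid "peak range" statistic for one-second
    epochs, laminar depth profiling and hippocampal layer assignment,
    speed-theta regressions, behavioural trial-epoch extraction, and linear
    mixed-effects comparisons of epoch statistics. A forward model generates
    synthetic laminar LFP, locomotion and trial data with known ground truth
    so the full chain is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
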