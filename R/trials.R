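## Behavioural trial-epoch extraction and condition tables.

#' Extract Hold/Run/Reward windows from a trial table
#'
#' Hold is `[stimulus_onset - 1.05, stimulus_onset - 0.05)`, Run the 1 s
#' before the peripheral response, and Reward the earliest 1 s window
#' after the response with every speed sample below 5 cm/s; trials that
#' never still yield no Reward window. All windows are exactly 1 s. By
#' default only correct, non-correction, non-aborted trials are used.
#' Overlapping Hold/Run windows (responses within 0.95 s of onset) are
#' both emitted with `overlap = TRUE`.
#'
#' @param trials trial table (see [generate_speed_trace()] for columns)
#' @param speed speed trace, cm/s at `fs`
#' @param fs sampling rate, Hz
#' @param include_errors keep error trials too
#' @param reward_thresh cm/s criterion for Reward stillness
#' @return data frame: `trial`, `label` (Hold/Run/Reward), `start`, `end`,
#'   `overlap`
#' @export
extract_trial_epochs <- function(trials, speed, fs, include_errors = FALSE,
                                 reward_thresh = 5) {
  keep <- !trials$aborted & !trials$correction_trial &
    (include_errors | trials$correct)
  trials <- trials[keep, , drop = FALSE]
  dur_s <- length(speed) / fs
  out <- list()
  for (i in seq_len(nrow(trials))) {
    onset <- trials$stimulus_onset[i]
    resp <- trials$response_time[i]
    overlap <- resp < onset + 0.95
    add <- function(label, start) {
      if (start >= 0 && start + 1 <= dur_s)
        out[[length(out) + 1]] <<- data.frame(
          trial = trials$trial[i], label = label, start = start,
          end = start + 1, overlap = overlap)
    }
    add("Hold", onset - 1.05)
    add("Run", resp - 1.0)
    rstart <- find_reward_window(speed, fs, resp, reward_thresh)
    if (!is.na(rstart)) add("Reward", rstart)
  }
  if (length(out) == 0)
    return(data.frame(trial = integer(0), label = character(0),
                      start = numeric(0), end = numeric(0),
                      overlap = logical(0)))
  do.call(rbind, out)
}

#' Peak-range condition table over trial-epoch windows
#'
#' Measures the autocorrelogram peak range and matched frequency inside
#' each trial-epoch window on each requested channel. Windows containing
#' masked LFP are dropped and counted. Optional normalisation divides
#' each channel's values by that channel's median Run value.
#'
#' @param session a `tq_session`
#' @param windows data frame from [extract_trial_epochs()]
#' @param channels channel indices
#' @param bank optional precomputed [sine_bank()]
#' @param normalise divide by the per-channel median Run value
#' @return list: `table` (one row per window per channel: `trial`,
#'   `condition`, `channel`, `peak_range`, `est_frequency`, `subject`,
#'   `session`), `n_dropped`
#' @export
epoch_condition_table <- function(session, windows, channels, bank = NULL,
                                  normalise = FALSE) {
  stopifnot(inherits(session, "tq_session"))
  profile <- session$species_profile
  fs <- session$recording$fs
  if (is.null(bank)) bank <- sine_bank(profile, fs)
  rows <- list()
  dropped <- 0L
  for (ch in channels) {
    x <- session$recording$samples[ch, ]
    x[!session$recording$valid_mask[ch, ]] <- NA
    filt <- prefilter_for_acg(x, profile, fs)
    for (i in seq_len(nrow(windows))) {
      i0 <- floor(windows$start[i] * fs) + 1L
      idx <- i0:(i0 + fs - 1L)
      if (idx[length(idx)] > length(filt)) { dropped <- dropped + 1L; next }
      seg <- filt[idx]
      if (anyNA(seg) || stats::sd(seg) == 0) { dropped <- dropped + 1L; next }
      acg <- autocorrelogram(seg)
      m <- match_sine(acg, bank)
      rows[[length(rows) + 1]] <- data.frame(
        trial = windows$trial[i], condition = windows$label[i],
        channel = ch, peak_range = peak_range(acg, m, fs),
        est_frequency = m$frequency,
        subject = session$meta$subject %||% NA_character_,
        session = session$meta$session %||% NA_character_)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab) && normalise) {
    for (ch in unique(tab$channel)) {
      sel <- tab$channel == ch
      run_med <- stats::median(tab$peak_range[sel & tab$condition == "Run"],
                               na.rm = TRUE)
      tab$peak_range[sel] <- tab$peak_range[sel] / run_med
    }
  }
  list(table = tab, n_dropped = dropped)
}

#' Behavioural performance summary
#'
#' Proportion correct per session and modality (correction trials
#' excluded), with a one-sample t-test across sessions against chance
#' (1 / `n_choices`). Degenerate zero-variance cases are flagged instead
#' of erroring.
#'
#' @param trials trial table with `correct`, `modality`,
#'   `correction_trial`, `aborted`, and optionally `session`
#' @param n_choices number of response locations (chance = 1/n)
#' @return list: `per_session` (data frame), `tests` (per modality:
#'   `mean_prop`, `t`, `p`, `degenerate` flag), `chance`
#' @export
behavioural_performance <- function(trials, n_choices) {
  scored <- trials[!trials$correction_trial & !trials$aborted, , drop = FALSE]
  if (nrow(scored) == 0) stop("no scored trials", call. = FALSE)
  if (is.null(scored$session)) scored$session <- "s1"
  chance <- 1 / n_choices
  per <- stats::aggregate(correct ~ session + modality, data = scored,
                          FUN = mean)
  names(per)[names(per) == "correct"] <- "prop_correct"
  tests <- lapply(split(per, per$modality), function(d) {
    p <- d$prop_correct
    if (length(p) < 2 || stats::sd(p) == 0)
      return(list(mean_prop = mean(p), t = NA_real_, p = NA_real_,
                  degenerate = TRUE))
    tt <- stats::t.test(p, mu = chance)
    list(mean_prop = mean(p), t = unname(tt$statistic), p = tt$p.value,
         degenerate = FALSE)
  })
  list(per_session = per, tests = tests, chance = chance)
}
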