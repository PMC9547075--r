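fs <- 1000

test_that("Hold/Run window arithmetic is exact", {
  trials <- data.frame(trial = 1L, hold_start = 6.5, stimulus_onset = 10.0,
                       modality = "A", target_location = 1,
                       response_time = 14.0, response_location = 1,
                       correct = TRUE, correction_trial = FALSE,
                       aborted = FALSE)
  speed <- rep(30, 20 * fs)
  speed[14301:16000] <- 1                     # stills from 14.3 s
  w <- extract_trial_epochs(trials, speed, fs)
  hold <- w[w$label == "Hold", ]
  expect_equal(hold$start, 10.0 - 1.05)
  expect_equal(hold$end, 10.0 - 0.05)
  run <- w[w$label == "Run", ]
  expect_equal(run$start, 13.0)
  expect_equal(run$end, 14.0)
  rwd <- w[w$label == "Reward", ]
  expect_equal(rwd$start, 14.3)
  expect_true(all(abs(w$end - w$start - 1) < 1e-9))
})

test_that("reward windows require a full second of stillness", {
  trials <- data.frame(trial = 1L, hold_start = 1, stimulus_onset = 4.5,
                       modality = "V", target_location = 2,
                       response_time = 8.0, response_location = 2,
                       correct = TRUE, correction_trial = FALSE,
                       aborted = FALSE)
  # never stills: no Reward window
  w <- extract_trial_epochs(trials, rep(30, 20 * fs), fs)
  expect_false("Reward" %in% w$label)
  expect_true(all(c("Hold", "Run") %in% w$label))
  # max speed inside every reward window < 5 post-hoc
  speed <- rep(30, 20 * fs); speed[8501:11000] <- 2
  speed[9000] <- 6                            # brief twitch pushes start later
  w2 <- extract_trial_epochs(trials, speed, fs)
  rwd <- w2[w2$label == "Reward", ]
  i0 <- round(rwd$start * fs) + 1
  expect_true(max(speed[i0:(i0 + fs - 1)]) < 5)
  expect_gte(rwd$start, 9000 / fs)
})

test_that("error/correction/aborted trials are excluded by default", {
  trials <- data.frame(trial = 1:4, hold_start = c(1, 21, 41, 61),
                       stimulus_onset = c(4, 24, 44, 64),
                       modality = "A", target_location = 1,
                       response_time = c(8, 28, 48, 68),
                       response_location = 1,
                       correct = c(TRUE, FALSE, TRUE, TRUE),
                       correction_trial = c(FALSE, FALSE, TRUE, FALSE),
                       aborted = c(FALSE, FALSE, FALSE, TRUE))
  speed <- rep(30, 80 * fs)
  w <- extract_trial_epochs(trials, speed, fs)
  expect_equal(sort(unique(w$trial)), 1L)
  w_err <- extract_trial_epochs(trials, speed, fs, include_errors = TRUE)
  expect_equal(sort(unique(w_err$trial)), c(1L, 2L))
})

test_that("overlapping Hold/Run windows are flagged, not dropped", {
  trials <- data.frame(trial = 1L, hold_start = 1, stimulus_onset = 4,
                       modality = "A", target_location = 1,
                       response_time = 4.5, response_location = 1,
                       correct = TRUE, correction_trial = FALSE,
                       aborted = FALSE)
  w <- extract_trial_epochs(trials, rep(30, 10 * fs), fs)
  expect_true(all(w$overlap))
  expect_true(all(c("Hold", "Run") %in% w$label))
})

test_that("condition tables reproduce the species trial-epoch contrasts", {
  g <- fix_session("ferret", duration_s = 240)
  s <- g$session
  w <- extract_trial_epochs(s$trials, s$speed, 1000)
  srslm <- g$truth$layers$srslm
  res <- epoch_condition_table(s, w, channels = srslm,
                               bank = fix_bank("ferret"))
  tab <- res$table
  med <- function(cond) median(tab$peak_range[tab$condition == cond],
                               na.rm = TRUE)
  # reward enhancement in the ferret SR/SLM
  expect_gt(med("Reward"), med("Run"))
  # bookkeeping: rows + drops = windows
  expect_equal(nrow(tab) + res$n_dropped, nrow(w))
  # normalisation: median of normalised Run values is exactly 1
  resn <- epoch_condition_table(s, w, channels = srslm,
                                bank = fix_bank("ferret"), normalise = TRUE)
  expect_equal(median(resn$table$peak_range[resn$table$condition == "Run"],
                      na.rm = TRUE), 1)
})

test_that("rat Run epochs dominate Hold and Reward", {
  g <- fix_session("rat", duration_s = 240)
  s <- g$session
  w <- extract_trial_epochs(s$trials, s$speed, 1000)
  res <- epoch_condition_table(s, w, channels = g$truth$layers$srslm,
                               bank = fix_bank("rat"))
  tab <- res$table
  med <- function(cond) median(tab$peak_range[tab$condition == cond],
                               na.rm = TRUE)
  expect_gt(med("Run"), med("Hold"))
  expect_gt(med("Run"), med("Reward"))
})

test_that("behavioural performance summarises proportions against chance", {
  trials <- data.frame(correct = c(rep(TRUE, 80), rep(FALSE, 20)),
                       modality = "A", correction_trial = FALSE,
                       aborted = FALSE, session = "s1")
  bp <- behavioural_performance(trials, n_choices = 5)
  expect_equal(bp$per_session$prop_correct, 0.8)
  expect_equal(bp$chance, 0.2)
  expect_true(bp$tests$A$degenerate)          # one session: no t-test
  # degenerate all-correct multi-session case flagged
  tr2 <- data.frame(correct = TRUE, modality = "V",
                    correction_trial = FALSE, aborted = FALSE,
                    session = rep(c("a", "b", "c"), each = 10))
  bp2 <- behavioural_performance(tr2, 5)
  expect_true(bp2$tests$V$degenerate)
  expect_error(behavioural_performance(
    data.frame(correct = logical(0), modality = character(0),
               correction_trial = logical(0), aborted = logical(0)), 5),
    "no scored")
})

test_that("performance test has power at realistic effect sizes", {
  set.seed(42)
  # 10 sessions of 30 trials at true p = 0.7 vs chance 0.2
  rejections <- replicate(200, {
    props <- rbinom(10, 30, 0.7) / 30
    t.test(props, mu = 0.2)$p.value < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})
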