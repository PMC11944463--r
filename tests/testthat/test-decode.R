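test_that("schemes select the right trials and stay disjoint", {
  pre <- small_preprocessed()
  meta <- pre$trial_meta
  s_all <- decoding_scheme("all_all")
  s_f0 <- decoding_scheme("full_to_f0")
  s_ti <- decoding_scheme("full_to_timbre")
  expect_equal(s_all$chance, 0.25)
  expect_equal(s_all$cv, "leave_one_trial_out")
  idx_all <- emodecode:::scheme_indices(pre, s_all)
  expect_equal(sort(idx_all$train),
               which(meta$emotion != "average"))
  idx_f0 <- emodecode:::scheme_indices(pre, s_f0)
  expect_length(intersect(idx_f0$train, idx_f0$test), 0)
  expect_true(all(meta$morph_condition[idx_f0$train] == "full"))
  expect_true(all(meta$morph_condition[idx_f0$test] == "f0"))
  idx_ti <- emodecode:::scheme_indices(pre, s_ti)
  expect_true(all(meta$morph_condition[idx_ti$test] == "timbre"))
  # a scheme with no test trials errors by name
  only_full <- subset_trials(pre, meta$morph_condition == "full")
  expect_error(decode_timepoint(only_full, 1, s_f0), "full_to_f0")
})

test_that("null decoding sits inside the chance band", {
  eeg <- null_eeg(n_trials = 192, n_channels = 16, n_time = 3)
  acc <- decode_timepoint(eeg, 2, decoding_scheme("all_all"))
  # central 99% binomial band around 0.25 for n = 192
  half <- 2.58 * sqrt(0.25 * 0.75 / 192)
  expect_gt(acc, 0.25 - half)
  expect_lt(acc, 0.25 + half)
})

test_that("noiseless distinct topographies decode perfectly", {
  cfg <- simulation_config(
    white_noise_sd = 0, pink_noise_sd = 0,
    effects = default_effects(amplitude = 2, window = c(500, 900)),
    eog_channels = FALSE, master_seed = 1)
  design <- small_design()
  eeg <- simulate_subject_eeg(small_trials(design), design,
                              musician_subject(), cfg)
  pre_cfg <- preprocess_config()
  pre <- preprocess_eeg(eeg, pre_cfg)
  tp <- which(pre$times == 700)
  acc <- decode_timepoint(pre, tp, decoding_scheme("full_to_f0"))
  expect_equal(acc, 1.0)
})

test_that("leave-one-out equals an explicit per-fold recount", {
  eeg <- null_eeg(n_trials = 48, n_channels = 6, n_time = 3, seed = 31)
  # nudge classes apart so accuracy is non-trivial
  for (k in seq_along(emotion_levels)) {
    sel <- eeg$trial_meta$emotion == emotion_levels[k]
    eeg$data[sel, k, ] <- eeg$data[sel, k, ] + 1.5
  }
  acc_fast <- decode_timepoint(eeg, 2, decoding_scheme("all_all"))
  # direct recount: n folds, each trial tested exactly once
  x <- eeg$data[, , 2]
  y <- eeg$trial_meta$emotion
  outcomes <- vapply(seq_len(nrow(x)), function(i) {
    fit <- train_lda(x[-i, , drop = FALSE], y[-i],
                     class_order = emotion_levels)
    predict_lda(fit, x[i, , drop = FALSE]) == y[i]
  }, logical(1))
  expect_length(outcomes, 48)
  expect_equal(acc_fast, mean(outcomes))
})

test_that("decoding is invariant to consistent channel permutation", {
  eeg <- null_eeg(n_trials = 40, n_channels = 8, n_time = 2, seed = 32)
  perm <- sample(8)
  eeg2 <- eeg
  eeg2$data <- eeg$data[, perm, , drop = FALSE]
  eeg2$channel_labels <- eeg$channel_labels[perm]
  expect_equal(decode_timepoint(eeg, 1, decoding_scheme("all_all")),
               decode_timepoint(eeg2, 1, decoding_scheme("all_all")))
})

test_that("a common-mode offset dies in the average reference", {
  eeg <- null_eeg(n_trials = 40, n_channels = 8, n_time = 2, seed = 33)
  shifted <- eeg
  shifted$data[, , 1] <- shifted$data[, , 1] + 7.3
  a <- rereference_average(eeg)
  b <- rereference_average(shifted)
  expect_equal(a$data, b$data, tolerance = 1e-10)
  expect_equal(decode_timepoint(a, 1, decoding_scheme("all_all")),
               decode_timepoint(b, 1, decoding_scheme("all_all")))
})

test_that("accuracy in the effect window is monotone in amplitude", {
  design <- build_stimulus_design(n_speakers = 2, n_words = 1)
  tt <- build_trial_table(design, n_reps = 4, n_blocks = 2, seed = 2)
  amps <- c(0, 2, 6)
  acc <- vapply(amps, function(a) {
    cfg <- simulation_config(effects = default_effects(amplitude = a),
                             eog_channels = FALSE, master_seed = 9)
    eeg <- simulate_subject_eeg(tt, design, musician_subject(), cfg)
    pre <- preprocess_eeg(eeg)
    tps <- which(pre$times %in% c(600, 700, 800))
    mean(vapply(tps, function(tp)
      decode_timepoint(pre, tp, decoding_scheme("all_all")), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > -0.03)) # non-decreasing up to sampling noise
  expect_gt(acc[3], acc[1] + 0.2)     # and clearly increasing overall
})

test_that("time-resolved decoding covers the post-onset grid", {
  pre <- small_preprocessed()
  tc <- time_resolved_decode(pre, "full_to_f0")
  expect_equal(tc$time_ms, seq(0, 990, by = 10))
  expect_true(all(tc$accuracy >= 0 & tc$accuracy <= 1))
  expect_equal(unique(tc$n_test_trials), sum(
    pre$trial_meta$morph_condition == "f0"))
  expect_false(any(tc$smoothed))
  tc_b <- time_resolved_decode(pre, "full_to_f0", include_baseline = TRUE)
  expect_equal(tc_b$time_ms, seq(-200, 990, by = 10))
})

test_that("effect-window accuracy is elevated only inside the window", {
  pre <- small_preprocessed() # default musician config, effects 500-900
  tc <- smooth_timecourse(time_resolved_decode(pre, "full_to_f0"))
  inwin <- tc$time_ms >= 500 & tc$time_ms < 900
  # outside the window (excluding smoothing bleed at the edges)
  outwin <- tc$time_ms < 450 | tc$time_ms >= 950
  expect_gt(mean(tc$accuracy[inwin]), 0.40)
  expect_lt(abs(mean(tc$accuracy[outwin]) - 0.25), 0.04)
})

test_that("smoothing implements the truncated centered rolling mean", {
  tc <- tibble::tibble(subject_id = "s", group = "g", scheme = "all_all",
                       time_ms = seq(0, 40, 10), accuracy = 1:5,
                       n_test_trials = 10L, smoothed = FALSE)
  class(tc) <- c("accuracy_timecourse", class(tc))
  sm <- smooth_timecourse(tc, 5)
  expect_equal(sm$accuracy, c(2, 2.5, 3, 3.5, 4)) # edges truncated
  expect_true(all(sm$smoothed))
  # window 1 is the identity; constant curves are unchanged
  expect_equal(smooth_timecourse(tc, 1)$accuracy, as.numeric(1:5))
  tc$accuracy <- rep(0.3, 5)
  expect_equal(smooth_timecourse(tc, 5)$accuracy, rep(0.3, 5))
  expect_error(smooth_timecourse(tc, 4), "odd")
})

test_that("timecourses round-trip through TSV", {
  pre <- small_preprocessed()
  tc <- time_resolved_decode(pre, "full_to_f0")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_timecourse(tc, f)
  tc2 <- read_timecourse(f)
  expect_equal(tibble::as_tibble(tc2), tibble::as_tibble(tc))
})
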