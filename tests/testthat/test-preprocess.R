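make_eeg <- function(data, rate, t0 = -200) {
  d <- dim(data)
  epoched_eeg(data, rate, t0 + (seq_len(d[3]) - 1) * 1000 / rate,
              sprintf("Ch%02d", seq_len(d[2])),
              tibble::tibble(trial_index = seq_len(d[1])))
}

test_that("resampling changes length, preserves constants, refuses to upsample", {
  # 1200 ms at 250 Hz (300 samples) -> 120 samples at 100 Hz
  eeg <- make_eeg(array(5, dim = c(2, 3, 300)), 250)
  out <- resample_eeg(eeg, 100)
  expect_equal(dim(out$data), c(2, 3, 120))
  expect_equal(out$sampling_rate, 100)
  expect_equal(out$times, seq(-200, 990, by = 10))
  # constant trace -> constant after detrend/resample/restore
  expect_equal(out$data, array(5, dim = c(2, 3, 120)), tolerance = 1e-10)
  expect_error(resample_eeg(eeg, 500), "upsample")
})

test_that("resampling preserves linear trends exactly", {
  t_old <- seq(-200, 998, by = 2)
  trend <- 0.01 * t_old + 3
  eeg <- make_eeg(array(rep(trend, each = 1), dim = c(1, 1, 600)), 500)
  out <- resample_eeg(eeg, 100)
  expect_equal(out$data[1, 1, ], 0.01 * out$times + 3, tolerance = 1e-9)
})

test_that("resampling keeps passband amplitude and rejects aliases", {
  rate <- 500
  t_s <- (0:599) / rate # 1.2 s
  amp_at <- function(x, f, r) {
    n <- length(x)
    k <- round(f * n / r) + 1
    2 * Mod(fft(x))[k] / n
  }
  # 10 Hz unit sine (12 full cycles in 1.2 s): amplitude within 1%
  s10 <- sin(2 * pi * 10 * t_s)
  eeg <- make_eeg(array(s10, dim = c(1, 1, 600)), rate)
  out <- resample_eeg(eeg, 250)
  expect_equal(amp_at(out$data[1, 1, ], 10, 250), 1, tolerance = 0.01)
  # 140 Hz sine is beyond the new 125 Hz Nyquist: >= 20 dB down at the
  # aliased frequency (250 - 140 = 110 Hz) and everywhere
  s140 <- sin(2 * pi * 140 * t_s)
  eeg2 <- make_eeg(array(s140, dim = c(1, 1, 600)), rate)
  out2 <- resample_eeg(eeg2, 250)
  spec <- Mod(fft(out2$data[1, 1, ]))[2:150] * 2 / 300
  expect_lt(20 * log10(max(spec) / 1), -20)
})

test_that("average reference zeroes the scalp mean and is idempotent", {
  # two channels [4, 2] -> [1, -1]
  eeg <- make_eeg(array(c(4, 2), dim = c(1, 2, 1)), 100)
  out <- rereference_average(eeg)
  expect_equal(as.numeric(out$data), c(1, -1))
  set.seed(1)
  eeg64 <- make_eeg(array(rnorm(5 * 64 * 30), dim = c(5, 64, 30)), 100)
  ref <- rereference_average(eeg64)
  means <- apply(ref$data, c(1, 3), mean)
  expect_true(all(abs(means) < 1e-10))
  expect_equal(rereference_average(ref)$data, ref$data, tolerance = 1e-12)
  expect_error(rereference_average(make_eeg(array(1, c(1, 1, 4)), 100)),
               ">= 2 scalp channels")
})

test_that("EOG channels are excluded from the reference and untouched", {
  data <- array(rnorm(2 * 6 * 10), dim = c(2, 6, 10))
  eeg <- epoched_eeg(data, 100, (0:9) * 10,
                     c(sprintf("Ch%02d", 1:4), "EXG1", "EXG2"),
                     tibble::tibble(trial_index = 1:2))
  out <- rereference_average(eeg)
  expect_equal(out$data[, 5:6, ], data[, 5:6, ])
  expect_true(all(abs(apply(out$data[, 1:4, ], c(1, 3), mean)) < 1e-10))
})

test_that("segmentation indexes the record correctly and checks bounds", {
  rate <- 250
  cont <- continuous_eeg(matrix(seq_len(2 * 2500), 2, byrow = TRUE), rate,
                         c("Ch01", "Ch02")) # 10 s record
  out <- segment_epochs(cont, 5000, c(-200, 1000))
  expect_equal(dim(out$data), c(1, 2, 300))
  # -200 ms before a 5000 ms onset at 250 Hz = sample 1200 (0-based)
  expect_equal(out$data[1, 1, 1], cont$data[1, 1201])
  expect_equal(out$times, seq(-200, 996, by = 4))
  expect_error(segment_epochs(cont, 100, c(-200, 1000)), "trial 1")
  empty <- segment_epochs(cont, numeric(0), c(-200, 1000))
  expect_equal(dim(empty$data)[1], 0)
})

test_that("baseline correction subtracts the pre-stimulus mean", {
  eeg <- make_eeg(array(3, dim = c(1, 1, 120)), 100)
  out <- baseline_correct(eeg)
  expect_true(all(out$data == 0))
  # 3 uV baseline, 7 uV post-stimulus -> 0 and 4
  x <- ifelse(eeg$times < 0, 3, 7)
  eeg2 <- make_eeg(array(x, dim = c(1, 1, 120)), 100)
  out2 <- baseline_correct(eeg2)
  expect_equal(as.numeric(out2$data[1, 1, ]), ifelse(eeg2$times < 0, 0, 4))
  set.seed(2)
  eeg3 <- make_eeg(array(rnorm(4 * 8 * 120), dim = c(4, 8, 120)), 100)
  out3 <- baseline_correct(eeg3)
  bl <- apply(out3$data[, , out3$times < 0], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-12))
  expect_error(baseline_correct(eeg, c(-500, -300)), "no samples")
})

test_that("full chain yields 64 channels x 120 timepoints on the 10 ms grid", {
  pre <- small_preprocessed()
  expect_equal(dim(pre$data)[2:3], c(64, 120))
  expect_equal(pre$sampling_rate, 100)
  expect_equal(pre$times, seq(-200, 990, by = 10))
  expect_false(any(emodecode:::is_eog_label(pre$channel_labels)))
  # trial metadata passes through untouched
  expect_equal(pre$trial_meta$emotion,
               simulate_subject_eeg(small_trials(), small_design(),
                                    musician_subject(),
                                    simulation_config(master_seed = 3)
                                    )$trial_meta$emotion)
  # all-zero input stays all-zero
  zero <- make_eeg(array(0, dim = c(2, 64, 600)), 500)
  outz <- preprocess_eeg(zero)
  expect_true(all(outz$data == 0))
  expect_error(preprocess_eeg(make_eeg(array(0, c(1, 4, 60)), 50)),
               "below first_resample_rate")
})

test_that("average reference and baseline correction commute", {
  set.seed(3)
  eeg <- make_eeg(array(rnorm(3 * 8 * 120), dim = c(3, 8, 120)), 100)
  ab <- baseline_correct(rereference_average(eeg))
  ba <- rereference_average(baseline_correct(eeg))
  expect_equal(ab$data, ba$data, tolerance = 1e-9)
})

test_that("preprocessing is deterministic and config is validated", {
  eeg <- simulate_subject_eeg(small_trials(), small_design(),
                              musician_subject(),
                              simulation_config(master_seed = 6))
  expect_identical(preprocess_eeg(eeg)$data, preprocess_eeg(eeg)$data)
  expect_error(preprocess_config(final_rate = 300), "<=")
  expect_error(preprocess_config(baseline_window = c(-300, 0)),
               "inside epoch_window")
})
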