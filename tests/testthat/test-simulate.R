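test_that("zero noise and zero amplitudes give all-zero data", {
  cfg <- simulation_config(white_noise_sd = 0, pink_noise_sd = 0,
                           effects = default_effects(amplitude = 0),
                           eog_channels = FALSE, master_seed = 1)
  eeg <- simulate_subject_eeg(small_trials(), small_design(),
                              musician_subject(), cfg)
  expect_true(all(eeg$data == 0))
  expect_equal(dim(eeg$data), c(104, 64, 600))
})

test_that("noiseless effect equals amplitude x topography in-window", {
  amp <- 3.7
  cfg <- simulation_config(
    white_noise_sd = 0, pink_noise_sd = 0,
    effects = default_effects(amplitude = amp, window = c(500, 900),
                              topography_seed = 77),
    envelope = "rectangular", eog_channels = FALSE, master_seed = 1)
  design <- small_design()
  eeg <- simulate_subject_eeg(small_trials(design), design,
                              musician_subject(), cfg)
  topo <- emodecode:::class_topographies(64, 77L, 1)
  meta <- eeg$trial_meta
  inwin <- eeg$times >= 500 & eeg$times < 900
  # an applicable trial: musician group + full morph + real emotion
  i <- which(meta$morph_condition == "full")[1]
  emo <- meta$emotion[i]
  expect_equal(eeg$data[i, , inwin],
               matrix(amp * topo[, emo], 64, sum(inwin)))
  expect_true(all(eeg$data[i, , !inwin] == 0))
  # timbre trials carry no effect (zero default amplitude)
  j <- which(meta$morph_condition == "timbre")[1]
  expect_true(all(eeg$data[j, , ] == 0))
  # emotional-average trials never receive an effect
  k <- which(meta$emotion == "average")[1]
  expect_true(all(eeg$data[k, , ] == 0))
})

test_that("raised-cosine envelope ramps between 0 and 1 inside the window", {
  cfg <- simulation_config(
    white_noise_sd = 0, pink_noise_sd = 0,
    effects = default_effects(amplitude = 1, window = c(500, 900)),
    envelope = "cosine", ramp_ms = 100, eog_channels = FALSE)
  design <- small_design()
  eeg <- simulate_subject_eeg(small_trials(design), design,
                              musician_subject(), cfg)
  i <- which(eeg$trial_meta$morph_condition == "full")[1]
  ch <- which.max(abs(eeg$data[i, , eeg$times == 700]))
  prof <- eeg$data[i, ch, ] / eeg$data[i, ch, eeg$times == 700]
  expect_equal(max(prof), 1)
  mid <- prof[eeg$times == 550] # halfway up the 100 ms ramp
  expect_equal(mid, 0.5, tolerance = 1e-6)
  expect_true(all(prof[eeg$times < 500] == 0))
})

test_that("simulation is bit-identical under identical seeds", {
  cfg <- simulation_config(master_seed = 17)
  a <- simulate_subject_eeg(small_trials(), small_design(),
                            musician_subject(), cfg)
  b <- simulate_subject_eeg(small_trials(), small_design(),
                            musician_subject(), cfg)
  expect_identical(a$data, b$data)
  c <- simulate_subject_eeg(small_trials(), small_design(),
                            musician_subject(seed = 99), cfg)
  expect_false(identical(a$data, c$data))
})

test_that("with zero amplitudes the data ignore the emotion labels", {
  # label exchangeability under the null, by construction: relabelling
  # the trials changes nothing because the effect term is never applied
  cfg <- simulation_config(effects = default_effects(amplitude = 0),
                           master_seed = 8)
  design <- small_design()
  tt <- small_trials(design)
  shuffled <- design
  shuffled$emotion <- sample(shuffled$emotion)
  a <- simulate_subject_eeg(tt, design, musician_subject(), cfg)
  b <- simulate_subject_eeg(tt, shuffled, musician_subject(), cfg)
  expect_identical(a$data, b$data)
})

test_that("pink noise has a ~1/f^alpha spectrum over 1-40 Hz", {
  cfg <- simulation_config(white_noise_sd = 0, pink_noise_sd = 5,
                           pink_alpha = 1, channel_mixing = 0,
                           effects = default_effects(amplitude = 0),
                           eog_channels = FALSE, n_channels = 4,
                           master_seed = 5)
  design <- small_design()
  eeg <- simulate_subject_eeg(small_trials(design), design,
                              musician_subject(), cfg) # 208 trials
  n <- length(eeg$times)
  freqs <- (seq_len(n) - 1) * eeg$sampling_rate / n
  sel <- freqs >= 1 & freqs <= 40
  # average periodogram over trials and channels
  pgram <- matrix(0, n, 1)
  total <- 0
  for (i in seq_len(100)) {
    for (ch in 1:4) {
      pgram <- pgram + Mod(fft(eeg$data[i, ch, ]))^2
      total <- total + 1
    }
  }
  fit <- stats::lm(log(pgram[sel] / total) ~ log(freqs[sel]))
  slope <- unname(coef(fit)[2])
  expect_lt(slope, 0)
  expect_equal(slope, -1, tolerance = 0.3)
})

test_that("simulation config validates windows and amplitudes", {
  expect_error(simulation_config(pink_noise_sd = -1), ">= 0")
  expect_error(
    simulation_config(effects = default_effects(window = c(500, 1200))),
    "outside the epoch")
  expect_error(simulation_config(channel_mixing = 1.5), "\\[0, 1\\]")
  bad <- default_effects()
  bad$amplitude[1] <- -2
  expect_error(simulation_config(effects = bad), ">= 0")
})

test_that("EOG channels are appended with noise only", {
  cfg <- simulation_config(master_seed = 2)
  eeg <- simulate_subject_eeg(small_trials(), small_design(),
                              musician_subject(), cfg)
  expect_equal(dim(eeg$data)[2], 68)
  expect_equal(tail(eeg$channel_labels, 4), sprintf("EXG%d", 1:4))
  expect_equal(sum(emodecode:::is_eog_label(eeg$channel_labels)), 4)
})
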