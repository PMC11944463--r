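#' Default class-discriminative effect table
#'
#' One row per (group, morph condition) effect entry. The defaults encode
#' the generative assumption behind the experiment's musician results:
#' emotion information in the EEG of musicians between 500 and 900 ms for
#' full-spectrum and F0 morphs, a zero-amplitude timbre entry, and nothing
#' for non-musicians. All default entries share a topography seed, so the
#' per-emotion scalp patterns are identical across morph conditions — this
#' is what makes a classifier trained on full morphs generalize to F0
#' morphs.
#'
#' The default amplitude of 2.5 microvolt against the default ~9 microvolt
#' post-reference channel noise gives a pairwise between-class Mahalanobis
#' separation of about 3 across the 64 channels -- an effect a single
#' subject's classifier detects clearly, chosen so recovery tests probe the
#' localization of the method rather than its power.
#'
#' @param amplitude Effect amplitude in microvolt (default 2.5).
#' @param window Effect window in ms (default `c(500, 900)`).
#' @param topography_seed Seed of the per-emotion topography draw.
#' @return A tibble with columns `group`, `morph_condition`,
#'   `window_start`, `window_end`, `amplitude`, `topography_seed`.
#' @export
default_effects <- function(amplitude = 2.5, window = c(500, 900),
                            topography_seed = 101L) {
  tibble::tibble(
    group = "musician",
    morph_condition = c("full", "f0", "timbre"),
    window_start = window[1],
    window_end = window[2],
    amplitude = c(amplitude, amplitude, 0),
    topography_seed = as.integer(topography_seed)
  )
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic EEG generator: channel count
#' and acquisition rate, epoch window, the 1/f ("pink") and white noise
#' levels, spatial channel mixing, the class-discriminative effect entries,
#' and the master seed. The defaults state the simulated world: 64 scalp
#' channels (+4 EOG) sampled at 500 Hz over -200..1000 ms epochs, pink
#' noise of 10 microvolt with spectral exponent 1, white sensor noise of
#' 2 microvolt, and musician-only effects at 500-900 ms (see
#' [default_effects()]).
#'
#' @param n_channels Scalp channel count (default 64).
#' @param acquisition_rate Native sampling rate in Hz (default 500).
#' @param epoch_window Epoch limits in ms, half-open `[t0, t1)`
#'   (default `c(-200, 1000)`).
#' @param white_noise_sd White noise standard deviation, microvolt.
#' @param pink_noise_sd 1/f noise standard deviation, microvolt.
#' @param pink_alpha Spectral exponent of the 1/f^alpha noise (default 1).
#' @param channel_mixing Fraction in `[0, 1]` of pink-noise variance shared
#'   across channels (spatial correlation of the background activity).
#' @param effects Effect table as produced by [default_effects()].
#' @param class_topography_separation Scale applied to the per-emotion
#'   topographies (standard-normal over channels before scaling).
#' @param envelope Temporal envelope of the effect, `"rectangular"` or
#'   `"cosine"` (raised-cosine on/off ramps).
#' @param ramp_ms Ramp duration for the cosine envelope (default 50 ms).
#' @param eog_channels Append 4 noise-only EOG channels (`EXG1`..`EXG4`)?
#' @param master_seed Integer master seed of the whole simulation.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_channels = 64, acquisition_rate = 500,
                              epoch_window = c(-200, 1000),
                              white_noise_sd = 2, pink_noise_sd = 10,
                              pink_alpha = 1, channel_mixing = 0.3,
                              effects = default_effects(),
                              class_topography_separation = 1,
                              envelope = c("rectangular", "cosine"),
                              ramp_ms = 50, eog_channels = TRUE,
                              master_seed = 1L) {
  envelope <- match.arg(envelope)
  cfg <- list(n_channels = n_channels, acquisition_rate = acquisition_rate,
              epoch_window = epoch_window, white_noise_sd = white_noise_sd,
              pink_noise_sd = pink_noise_sd, pink_alpha = pink_alpha,
              channel_mixing = channel_mixing, effects = effects,
              class_topography_separation = class_topography_separation,
              envelope = envelope, ramp_ms = ramp_ms,
              eog_channels = eog_channels,
              master_seed = as.integer(master_seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$white_noise_sd < 0 || cfg$pink_noise_sd < 0) {
    stopf("noise standard deviations must be >= 0")
  }
  if (cfg$channel_mixing < 0 || cfg$channel_mixing > 1) {
    stopf("channel_mixing must lie in [0, 1]")
  }
  eff <- cfg$effects
  if (nrow(eff) > 0) {
    if (any(eff$amplitude < 0)) stopf("effect amplitudes must be >= 0")
    bad <- eff$window_start < cfg$epoch_window[1] |
      eff$window_end > cfg$epoch_window[2] |
      eff$window_start >= eff$window_end
    if (any(bad)) {
      stopf("effect window [%g, %g] ms falls outside the epoch [%g, %g] ms",
            eff$window_start[which(bad)[1]], eff$window_end[which(bad)[1]],
            cfg$epoch_window[1], cfg$epoch_window[2])
    }
  }
  invisible(cfg)
}

# 1/f^alpha noise, one column per channel, unit variance per column.
# FFT shaping: white spectrum scaled by f^(-alpha/2), DC removed.
pink_noise <- function(n, n_cols, alpha) {
  w <- matrix(rnorm(n * n_cols), n, n_cols)
  if (alpha == 0) return(w)
  fw <- mvfft(w)
  k <- c(0, seq_len(n - 1))
  f <- pmin(k, n - k) # frequency index, symmetric
  scale <- c(0, f[-1]^(-alpha / 2))
  x <- Re(mvfft(fw * scale, inverse = TRUE)) / n
  # renormalize each column to unit sd
  s <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, pmax(s, .Machine$double.eps), "/")
}

# Per-emotion scalp topographies: standard normal over channels, drawn from
# the effect's topography seed so they are stable across subjects/conditions.
class_topographies <- function(n_channels, topography_seed, separation) {
  topo <- withr_seed(topography_seed, {
    matrix(rnorm(n_channels * length(emotion_levels)), n_channels,
           length(emotion_levels))
  })
  colnames(topo) <- emotion_levels
  topo * separation
}

effect_envelope <- function(times, window, type, ramp_ms) {
  env <- as.numeric(times >= window[1] & times < window[2])
  if (type == "cosine" && ramp_ms > 0) {
    up <- times >= window[1] & times < window[1] + ramp_ms
    dn <- times >= window[2] - ramp_ms & times < window[2]
    env[up] <- 0.5 * (1 - cos(pi * (times[up] - window[1]) / ramp_ms))
    env[dn] <- 0.5 * (1 - cos(pi * (window[2] - times[dn]) / ramp_ms))
  }
  env
}

#' Simulate a subject's epoched EEG
#'
#' Generates one epoch per trial of the trial table: spatially correlated
#' 1/f background noise plus white sensor noise, plus -- for trials whose
#' (group, morph condition) matches an effect entry and whose emotion is
#' not "average" -- an additive class-discriminative signal
#' `amplitude * topography(emotion) * envelope(t)` confined to the effect
#' window. Emotional-average trials never receive a class effect, so under
#' zero amplitudes the data distribution is identical across emotion labels
#' by construction. The draw is reproducible from
#' `(config$master_seed, subject$seed)`.
#'
#' @param trial_table A `trial_table` tibble.
#' @param design The `stimulus_design` the trial table indexes into.
#' @param subject One-row tibble (or list) with `subject_id`, `group`,
#'   `seed`, e.g. a row of [build_cohort()].
#' @param config A [simulation_config()].
#' @return An [epoched_eeg()] at the native acquisition rate, with EOG
#'   channels appended when configured.
#' @export
simulate_subject_eeg <- function(trial_table, design, subject,
                                 config = simulation_config()) {
  validate_simulation_config(config)
  meta <- dplyr::left_join(
    tibble::as_tibble(trial_table),
    dplyr::select(tibble::as_tibble(design), "stimulus_id", "emotion",
                  "morph_condition"),
    by = "stimulus_id")
  n_tr <- nrow(meta)
  rate <- config$acquisition_rate
  win <- config$epoch_window
  n_t <- round((win[2] - win[1]) / 1000 * rate)
  times <- win[1] + (seq_len(n_t) - 1) * 1000 / rate
  n_scalp <- config$n_channels
  n_eog <- if (config$eog_channels) 4L else 0L
  n_ch <- n_scalp + n_eog

  # one topography matrix per distinct topography seed
  topo_by_seed <- lapply(
    setNames(nm = unique(config$effects$topography_seed)),
    function(s) class_topographies(n_scalp, as.integer(s),
                                   config$class_topography_separation))

  data <- array(0, dim = c(n_tr, n_ch, n_t))
  mix <- config$channel_mixing
  withr_seed(child_seed(config$master_seed, subject$seed), {
    for (i in seq_len(n_tr)) {
      epoch <- matrix(0, n_t, n_ch)
      if (config$pink_noise_sd > 0) {
        indep <- pink_noise(n_t, n_ch, config$pink_alpha)
        if (mix > 0) {
          common <- pink_noise(n_t, 1, config$pink_alpha)[, 1]
          epoch <- epoch + config$pink_noise_sd *
            (sqrt(1 - mix) * indep + sqrt(mix) * common)
        } else {
          epoch <- epoch + config$pink_noise_sd * indep
        }
      }
      if (config$white_noise_sd > 0) {
        epoch <- epoch + config$white_noise_sd *
          matrix(rnorm(n_t * n_ch), n_t, n_ch)
      }
      emo <- meta$emotion[i]
      if (emo %in% emotion_levels && nrow(config$effects) > 0) {
        eff <- config$effects[
          config$effects$group == subject$group &
            config$effects$morph_condition == meta$morph_condition[i] &
            config$effects$amplitude > 0, , drop = FALSE]
        for (j in seq_len(nrow(eff))) {
          env <- effect_envelope(times,
                                 c(eff$window_start[j], eff$window_end[j]),
                                 config$envelope, config$ramp_ms)
          topo <- topo_by_seed[[as.character(eff$topography_seed[j])]]
          epoch[, seq_len(n_scalp)] <- epoch[, seq_len(n_scalp)] +
            eff$amplitude[j] * outer(env, topo[, emo])
        }
      }
      data[i, , ] <- t(epoch)
    }
  })

  epoched_eeg(
    data = data, sampling_rate = rate, times = times,
    channel_labels = montage_labels(n_scalp, eog = config$eog_channels),
    trial_meta = meta,
    subject_id = as.character(subject$subject_id),
    group = as.character(subject$group))
}
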