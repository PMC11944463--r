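#' Preprocessing configuration
#'
#' Parameters of the minimal, filter-free preprocessing chain: a first
#' anti-aliased resample to 250 Hz, average reference, EOG-channel removal,
#' baseline correction over the pre-stimulus interval, and a final
#' anti-aliased downsample to 100 Hz (one sample per 10 ms bin). No
#' frequency filtering and no artifact or channel rejection are ever
#' applied.
#'
#' @param first_resample_rate First resampling target in Hz (default 250).
#' @param final_rate Final rate in Hz (default 100).
#' @param epoch_window Epoch limits in ms (default `c(-200, 1000)`).
#' @param baseline_window Baseline interval in ms, half-open
#'   (default `c(-200, 0)`).
#' @param drop_labels Channel labels removed before decoding (default the
#'   four `EXG` eye channels).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(first_resample_rate = 250, final_rate = 100,
                              epoch_window = c(-200, 1000),
                              baseline_window = c(-200, 0),
                              drop_labels = sprintf("EXG%d", 1:4)) {
  if (final_rate > first_resample_rate) {
    stopf("final_rate must be <= first_resample_rate")
  }
  if (baseline_window[1] < epoch_window[1] ||
      baseline_window[2] > epoch_window[2]) {
    stopf("baseline_window must lie inside epoch_window")
  }
  structure(list(first_resample_rate = first_resample_rate,
                 final_rate = final_rate, epoch_window = epoch_window,
                 baseline_window = baseline_window,
                 drop_labels = drop_labels),
            class = "preprocess_config")
}

int_gcd <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

# Reduce a rate ratio to the rational up/down factors L/M.
rate_factors <- function(target, source) {
  a <- round(target * 1000)
  b <- round(source * 1000)
  g <- int_gcd(a, b)
  c(L = a / g, M = b / g)
}

# Kaiser-windowed sinc anti-alias kernel for polyphase resampling by L/M:
# cutoff at the lower of the two Nyquist rates, gain L, beta = 8.6
# (~60 dB stopband), half-length 20 * max(L, M) taps at the upsampled
# rate. The taper makes the impulse-response tails die off quickly, so a
# sharp transient leaks only a few tens of ms.
resample_kernel <- function(L, M, half_factor = 20, beta = 8.6) {
  P <- half_factor * max(L, M)
  j <- (-P):P
  fc <- 1 / max(L, M)
  h <- fc * ifelse(j == 0, 1, sin(pi * fc * j) / (pi * fc * j))
  w <- besselI(beta * sqrt(pmax(0, 1 - (j / P)^2)), 0) / besselI(beta, 0)
  L * h * w
}

# Polyphase (zero-stuff -> FIR low-pass -> decimate) resampling of the
# columns of a matrix, zero-phase, zero-padded at the edges (callers
# detrend first so the ends sit near zero).
poly_resample_mat <- function(x, L, M) {
  n <- nrow(x)
  m <- round(n * L / M)
  h <- resample_kernel(L, M)
  P <- (length(h) - 1) / 2
  up <- matrix(0, n * L, ncol(x))
  up[seq(1, n * L, by = L), ] <- x
  nf <- stats::nextn(n * L + length(h) - 1)
  hf <- fft(c(h, rep(0, nf - length(h))))
  uf <- mvfft(rbind(up, matrix(0, nf - n * L, ncol(x))))
  conv <- Re(mvfft(uf * hf, inverse = TRUE)) / nf
  conv[P + 1 + (seq_len(m) - 1) * M, , drop = FALSE]
}

#' Anti-aliased resampling of epoched EEG
#'
#' Per epoch and channel: removes the linear trend (the line through the
#' epoch's first and last samples), resamples the residual with a
#' rational-factor polyphase FIR interpolator (Kaiser-windowed sinc
#' anti-alias low-pass), and restores the trend evaluated at the new
#' timepoints. The endpoint-bridge detrend leaves a residual that
#' vanishes at both epoch boundaries, so the zero-padded convolution
#' introduces no edge transients; trend restoration preserves DC
#' offsets, drifts and exact linear trends -- a constant trace stays
#' constant.
#'
#' @param eeg An [epoched_eeg()].
#' @param target_rate Target rate in Hz; must not exceed the current rate.
#' @return The resampled `epoched_eeg` with
#'   `round(n * target_rate / sampling_rate)` samples per epoch on the same
#'   epoch window.
#' @export
resample_eeg <- function(eeg, target_rate) {
  if (target_rate > eeg$sampling_rate) {
    stopf("cannot upsample: target_rate %g Hz exceeds sampling rate %g Hz",
          target_rate, eeg$sampling_rate)
  }
  if (target_rate == eeg$sampling_rate) return(eeg)
  d <- dim(eeg$data)
  n <- d[3]
  lm <- rate_factors(target_rate, eeg$sampling_rate)
  m <- round(n * target_rate / eeg$sampling_rate)
  t_old <- eeg$times
  t_new <- t_old[1] + (seq_len(m) - 1) * 1000 / target_rate
  # flatten to time x (trial*channel), chunked over trials to bound memory
  out <- array(0, dim = c(d[1], d[2], m))
  chunk <- max(1L, as.integer(2e6 / (n * d[2])))
  for (lo in seq(1, d[1], by = chunk)) {
    hi <- min(lo + chunk - 1, d[1])
    block <- eeg$data[lo:hi, , , drop = FALSE]
    k <- (hi - lo + 1) * d[2]
    x <- t(matrix(block, nrow = k, ncol = n)) # time x series
    # bridge detrend: the line through the epoch's end samples, so the
    # residual vanishes at both boundaries and the circular FFT sees no
    # wrap-around jump (which would ring into the epoch ends)
    slope <- (x[n, ] - x[1, ]) / (t_old[n] - t_old[1])
    first <- x[1, ]
    resid <- x - outer(t_old - t_old[1], slope) - rep(first, each = n)
    res_new <- poly_resample_mat(resid, lm["L"], lm["M"])
    trend_new <- outer(t_new - t_old[1], slope) + rep(first, each = m)
    y <- res_new + trend_new
    out[lo:hi, , ] <- aperm(array(t(y), dim = c(hi - lo + 1, d[2], m)),
                            c(1, 2, 3))
  }
  eeg$data <- out
  eeg$sampling_rate <- target_rate
  eeg$times <- t_new
  eeg
}

#' Average reference
#'
#' Subtracts, at every timepoint, the mean over scalp channels from each
#' scalp channel. EOG channels (labels matching `EXG`/`EOG`) are excluded
#' from the mean and left untouched. After the operation the scalp-channel
#' mean is zero at every timepoint of every trial.
#'
#' @param eeg An [epoched_eeg()].
#' @return The re-referenced `epoched_eeg`.
#' @export
rereference_average <- function(eeg) {
  scalp <- which(!is_eog_label(eeg$channel_labels))
  if (length(scalp) < 2) {
    stopf("average reference requires >= 2 scalp channels, found %d",
          length(scalp))
  }
  d <- eeg$data
  mean_tc <- apply(d[, scalp, , drop = FALSE], c(1, 3), mean)
  d[, scalp, ] <- d[, scalp, , drop = FALSE] -
    aperm(array(mean_tc, dim = c(dim(d)[1], dim(d)[3], length(scalp))),
          c(1, 3, 2))
  eeg$data <- d
  eeg
}

#' Continuous EEG container
#'
#' A channels x time matrix with its sampling rate and time axis, used by
#' the real-data path before epoching.
#'
#' @param data Numeric matrix `[channel, time]` in microvolt.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character channel names.
#' @param times Optional time axis in ms (default starts at 0).
#' @param subject_id,group Optional identifiers.
#' @return An object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, sampling_rate, channel_labels,
                           times = NULL, subject_id = NA_character_,
                           group = NA_character_) {
  times <- times %||% ((seq_len(ncol(data)) - 1) * 1000 / sampling_rate)
  structure(list(data = data, sampling_rate = sampling_rate,
                 times = times, channel_labels = channel_labels,
                 subject_id = subject_id, group = group),
            class = "continuous_eeg")
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' @param x A [continuous_eeg()].
#' @param event_onsets_ms Numeric vector of stimulus onsets, in the time
#'   axis of `x` (ms).
#' @param epoch_window Epoch limits in ms relative to onset, half-open
#'   `[t0, t1)`.
#' @param trial_meta Optional tibble of per-trial metadata (one row per
#'   onset).
#' @return An [epoched_eeg()]; zero onsets give an object with 0 trials.
#' @export
segment_epochs <- function(x, event_onsets_ms,
                           epoch_window = c(-200, 1000),
                           trial_meta = NULL) {
  rate <- x$sampling_rate
  n_samp <- round((epoch_window[2] - epoch_window[1]) / 1000 * rate)
  n_total <- ncol(x$data)
  n_ev <- length(event_onsets_ms)
  data <- array(0, dim = c(n_ev, nrow(x$data), n_samp))
  for (i in seq_len(n_ev)) {
    start <- round((event_onsets_ms[i] + epoch_window[1] - x$times[1]) *
                     rate / 1000) + 1L
    if (start < 1 || start + n_samp - 1 > n_total) {
      stopf("epoch for trial %d (onset %g ms) falls outside the recording",
            i, event_onsets_ms[i])
    }
    data[i, , ] <- x$data[, start:(start + n_samp - 1)]
  }
  times <- epoch_window[1] + (seq_len(n_samp) - 1) * 1000 / rate
  meta <- trial_meta %||% tibble::tibble(trial_index = seq_len(n_ev))
  epoched_eeg(data, rate, times, x$channel_labels, meta,
              subject_id = x$subject_id, group = x$group)
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean voltage over the pre-stimulus
#' baseline interval from the whole epoch.
#'
#' @param eeg An [epoched_eeg()].
#' @param baseline_window Baseline interval in ms, half-open `[t0, t1)`
#'   (default `c(-200, 0)`: all pre-stimulus samples).
#' @return The baseline-corrected `epoched_eeg`.
#' @export
baseline_correct <- function(eeg, baseline_window = c(-200, 0)) {
  idx <- which(eeg$times >= baseline_window[1] &
                 eeg$times < baseline_window[2])
  if (length(idx) == 0) {
    stopf("baseline window [%g, %g) ms contains no samples",
          baseline_window[1], baseline_window[2])
  }
  bl <- apply(eeg$data[, , idx, drop = FALSE], c(1, 2), mean)
  eeg$data <- eeg$data - array(bl, dim = dim(eeg$data))
  eeg
}

drop_channels <- function(eeg, labels) {
  keep <- !(eeg$channel_labels %in% labels)
  eeg$data <- eeg$data[, keep, , drop = FALSE]
  eeg$channel_labels <- eeg$channel_labels[keep]
  eeg
}

#' Full preprocessing chain
#'
#' Applies, in order: anti-aliased resample to `first_resample_rate`,
#' average reference, (epoch segmentation when the input is continuous),
#' EOG-channel removal, baseline correction, and anti-aliased downsample to
#' `final_rate`. Under the defaults a 500 Hz, 68-channel input becomes
#' 64 channels x 120 timepoints per trial on the -200, -190, ..., 990 ms
#' grid. No frequency filtering and no artifact or channel rejection are
#' performed at any stage, and per-trial metadata passes through unchanged.
#'
#' @param eeg An [epoched_eeg()] or [continuous_eeg()].
#' @param config A [preprocess_config()].
#' @param event_onsets_ms Stimulus onsets (ms), required for continuous
#'   input.
#' @param trial_meta Per-trial metadata for continuous input.
#' @return The preprocessed [epoched_eeg()] at `config$final_rate`.
#' @export
preprocess_eeg <- function(eeg, config = preprocess_config(),
                           event_onsets_ms = NULL, trial_meta = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("preprocessing stage '%s' failed: %s", name,
            conditionMessage(e))
    })
  }
  if (eeg$sampling_rate < config$first_resample_rate) {
    stopf("input rate %g Hz is below first_resample_rate %g Hz",
          eeg$sampling_rate, config$first_resample_rate)
  }
  continuous <- inherits(eeg, "continuous_eeg")
  if (continuous) {
    if (is.null(event_onsets_ms)) {
      stopf("continuous input requires event_onsets_ms")
    }
    if (eeg$sampling_rate > config$first_resample_rate) {
      m <- round(ncol(eeg$data) * config$first_resample_rate /
                   eeg$sampling_rate)
      tmp <- epoched_eeg(
        array(eeg$data, dim = c(1, dim(eeg$data))), eeg$sampling_rate,
        eeg$times, eeg$channel_labels, tibble::tibble(trial_index = 1L))
      tmp <- stage("resample", resample_eeg(tmp, config$first_resample_rate))
      eeg <- continuous_eeg(matrix(tmp$data[1, , ], dim(tmp$data)[2]),
                            config$first_resample_rate,
                            eeg$channel_labels, times = tmp$times,
                            subject_id = eeg$subject_id, group = eeg$group)
    }
    eeg$data <- stage("average reference", {
      scalp <- which(!is_eog_label(eeg$channel_labels))
      if (length(scalp) < 2) stopf(">= 2 scalp channels required")
      d <- eeg$data
      d[scalp, ] <- sweep(d[scalp, , drop = FALSE], 2,
                          colMeans(d[scalp, , drop = FALSE]))
      d
    })
    eeg <- stage("segmentation",
                 segment_epochs(eeg, event_onsets_ms, config$epoch_window,
                                trial_meta))
  } else {
    eeg <- stage("resample", resample_eeg(eeg, config$first_resample_rate))
    eeg <- stage("average reference", rereference_average(eeg))
  }
  eeg <- stage("channel removal", drop_channels(eeg, config$drop_labels))
  eeg <- stage("baseline correction",
               baseline_correct(eeg, config$baseline_window))
  eeg <- stage("final resample", resample_eeg(eeg, config$final_rate))
  eeg
}
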