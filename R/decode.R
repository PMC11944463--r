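#' Decoding schemes
#'
#' The three training/testing schemes of the analysis:
#' \describe{
#'   \item{`all_all`}{train and test on all emotional trials (full, F0 and
#'     timbre morphs) under leave-one-trial-out cross-validation;}
#'   \item{`full_to_f0`}{train once on all full-morph trials, test on all
#'     F0-morph trials (disjoint sets, no fold structure);}
#'   \item{`full_to_timbre`}{train on full morphs, test on timbre morphs.}
#' }
#' Emotional-average trials are excluded from every scheme: decoding is
#' always the 4-class emotion problem with chance level 0.25. Prompt
#' trials are retained.
#'
#' @param name One of `"all_all"`, `"full_to_f0"`, `"full_to_timbre"`.
#' @return A list of class `decoding_scheme` with `name`, `train_morphs`,
#'   `test_morphs`, `cv` (`"leave_one_trial_out"` or
#'   `"disjoint_train_test"`), `n_classes = 4`, `chance = 0.25`.
#' @export
decoding_scheme <- function(name = c("all_all", "full_to_f0",
                                     "full_to_timbre")) {
  name <- match.arg(name)
  spec <- switch(name,
    all_all = list(train = morph_levels, test = morph_levels,
                   cv = "leave_one_trial_out"),
    full_to_f0 = list(train = "full", test = "f0",
                      cv = "disjoint_train_test"),
    full_to_timbre = list(train = "full", test = "timbre",
                          cv = "disjoint_train_test"))
  structure(list(name = name, train_morphs = spec$train,
                 test_morphs = spec$test, cv = spec$cv,
                 n_classes = 4L, chance = 0.25),
            class = "decoding_scheme")
}

scheme_indices <- function(eeg, scheme) {
  meta <- eeg$trial_meta
  emotional <- meta$emotion %in% emotion_levels
  train <- which(emotional & meta$morph_condition %in% scheme$train_morphs)
  test <- which(emotional & meta$morph_condition %in% scheme$test_morphs)
  if (length(test) == 0) {
    stopf("scheme '%s' selects no test trials", scheme$name)
  }
  if (scheme$cv == "disjoint_train_test" &&
      length(intersect(train, test)) > 0) {
    stopf("scheme '%s' places trials in both train and test sets",
          scheme$name)
  }
  list(train = train, test = test)
}

#' Decode one timepoint
#'
#' Classifies the four emotions from the 64 channel voltages at a single
#' sample of the 100 Hz grid (one 10 ms bin). Under leave-one-trial-out
#' the classifier is retrained `n` times, each fold holding out one trial,
#' and the accuracy is the mean of the per-fold 0/1 outcomes; under the
#' cross-morph schemes the classifier is trained once on the training
#' morphs and scored on every test-morph trial.
#'
#' @param eeg A preprocessed [epoched_eeg()].
#' @param timepoint_index Index into `eeg$times`.
#' @param scheme A [decoding_scheme()].
#' @param lambda LDA shrinkage (default 0.01).
#' @return Scalar accuracy in `[0, 1]`.
#' @export
decode_timepoint <- function(eeg, timepoint_index,
                             scheme = decoding_scheme("all_all"),
                             lambda = 0.01) {
  idx <- scheme_indices(eeg, scheme)
  x <- eeg$data[, , timepoint_index]
  if (is.null(dim(x))) x <- matrix(x, nrow = dim(eeg$data)[1])
  y <- eeg$trial_meta$emotion
  if (scheme$cv == "leave_one_trial_out") {
    xi <- x[idx$train, , drop = FALSE]
    yi <- match(y[idx$train], emotion_levels)
    cpp_lda_loto(xi, yi, length(emotion_levels), lambda)
  } else {
    fit <- train_lda(x[idx$train, , drop = FALSE], y[idx$train],
                     lambda = lambda, class_order = emotion_levels)
    pred <- predict_lda(fit, x[idx$test, , drop = FALSE])
    mean(pred == y[idx$test])
  }
}

#' Time-resolved decoding
#'
#' Runs [decode_timepoint()] at every post-onset timepoint (optionally
#' also over the pre-stimulus baseline, as a diagnostic) and returns the
#' unsmoothed accuracy timecourse.
#'
#' @param eeg A preprocessed [epoched_eeg()] on the 100 Hz grid.
#' @param scheme A [decoding_scheme()] or scheme name.
#' @param include_baseline Decode pre-stimulus timepoints too?
#'   Default `FALSE`.
#' @param lambda LDA shrinkage (default 0.01).
#' @return An `accuracy_timecourse` tibble with columns `subject_id`,
#'   `group`, `scheme`, `time_ms`, `accuracy`, `n_test_trials`,
#'   `smoothed`.
#' @export
time_resolved_decode <- function(eeg, scheme = decoding_scheme("all_all"),
                                 include_baseline = FALSE, lambda = 0.01) {
  if (is.character(scheme)) scheme <- decoding_scheme(scheme)
  idx <- scheme_indices(eeg, scheme)
  tp <- if (include_baseline) seq_along(eeg$times) else
    which(eeg$times >= 0)
  y <- match(eeg$trial_meta$emotion, emotion_levels)
  acc <- if (scheme$cv == "leave_one_trial_out") {
    as.numeric(cpp_lda_loto_timecourse(eeg$data, idx$train, y, tp,
                                       length(emotion_levels), lambda))
  } else {
    vapply(tp, function(t) decode_timepoint(eeg, t, scheme, lambda),
           numeric(1))
  }
  tc <- tibble::tibble(
    subject_id = eeg$subject_id, group = eeg$group, scheme = scheme$name,
    time_ms = eeg$times[tp], accuracy = acc,
    n_test_trials = length(idx$test), smoothed = FALSE)
  class(tc) <- c("accuracy_timecourse", class(tc))
  tc
}

#' Rolling-mean smoothing of accuracy timecourses
#'
#' Centered moving average with an odd window (default 5 timepoints, i.e.
#' 50 ms at 100 Hz), truncated at the epoch edges so the first and last
#' values average fewer points. Group inference always runs on smoothed
#' curves.
#'
#' @param tc An `accuracy_timecourse` tibble (may hold several subjects
#'   and schemes; smoothing is applied within each).
#' @param window Odd window length in timepoints (default 5); `1` is the
#'   identity.
#' @return The smoothed `accuracy_timecourse` with `smoothed = TRUE`.
#' @export
smooth_timecourse <- function(tc, window = 5) {
  if (window < 1 || window %% 2 == 0) {
    stopf("smoothing window must be odd and >= 1, got %g", window)
  }
  half <- (window - 1) / 2
  out <- tc |>
    dplyr::group_by(.data$subject_id, .data$group, .data$scheme) |>
    dplyr::arrange(.data$time_ms, .by_group = TRUE) |>
    dplyr::mutate(accuracy = rolling_mean(.data$accuracy, half),
                  smoothed = TRUE) |>
    dplyr::ungroup()
  class(out) <- c("accuracy_timecourse", class(out))
  out
}

rolling_mean <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Write/read accuracy timecourses as TSV
#'
#' @param tc An `accuracy_timecourse` tibble.
#' @param path File path.
#' @return `read_timecourse()` returns the tibble with class restored.
#' @export
write_timecourse <- function(tc, path) {
  readr::write_tsv(tibble::as_tibble(tc), path)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         subject_id = "c", group = "c", scheme = "c",
                         time_ms = "d", accuracy = "d",
                         n_test_trials = "i", smoothed = "l"))
  class(x) <- c("accuracy_timecourse", class(x))
  x
}
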