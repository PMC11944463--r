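#' Epoched EEG container
#'
#' A trials x channels x timepoints array of voltages (microvolt) with its
#' time axis, sampling rate, channel labels and per-trial metadata. This is
#' the object every preprocessing and decoding stage consumes and returns.
#'
#' @param data Numeric array `[trial, channel, timepoint]` in microvolt.
#' @param sampling_rate Sampling rate in Hz.
#' @param times Numeric vector of timepoints in ms relative to stimulus
#'   onset; must be strictly increasing with uniform spacing
#'   `1000 / sampling_rate`.
#' @param channel_labels Character vector of channel names (extended 10-20
#'   scheme; EOG channels, if present, are labelled `EXG1`..`EXG4`).
#' @param trial_meta Tibble with one row per trial; must contain `emotion`
#'   and `morph_condition` for decoding.
#' @param subject_id,group Subject identifier and group label.
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, sampling_rate, times, channel_labels,
                        trial_meta, subject_id = NA_character_,
                        group = NA_character_) {
  obj <- structure(
    list(data = data, sampling_rate = sampling_rate, times = times,
         channel_labels = channel_labels,
         trial_meta = tibble::as_tibble(trial_meta),
         subject_id = subject_id, group = group),
    class = "epoched_eeg")
  validate_epoched_eeg(obj)
  obj
}

validate_epoched_eeg <- function(x) {
  d <- dim(x$data)
  if (length(d) != 3) stopf("data must be a 3-d array [trial, channel, time]")
  if (length(x$times) != d[3]) {
    stopf("times has length %d but data has %d timepoints",
          length(x$times), d[3])
  }
  if (length(x$channel_labels) != d[2]) {
    stopf("channel_labels has length %d but data has %d channels",
          length(x$channel_labels), d[2])
  }
  if (nrow(x$trial_meta) != d[1]) {
    stopf("trial_meta has %d rows but data has %d trials",
          nrow(x$trial_meta), d[1])
  }
  if (length(x$times) > 1) {
    dt <- diff(x$times)
    if (any(dt <= 0)) stopf("times must be strictly increasing")
    step <- 1000 / x$sampling_rate
    if (any(abs(dt - step) > 1e-6)) {
      stopf("times spacing must be uniform at %g ms (1000/sampling_rate)",
            step)
    }
  }
  invisible(x)
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> subject %s (%s)\n", x$subject_id, x$group))
  cat(sprintf("  %d trials x %d channels x %d timepoints @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  epoch %g..%g ms\n", min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.epoched_eeg <- function(x) dim(x$data)

n_trials <- function(eeg) dim(eeg$data)[1]

#' Subset trials of an epoched EEG object
#'
#' @param eeg An `epoched_eeg` object.
#' @param idx Logical or integer trial index.
#' @return An `epoched_eeg` containing only the selected trials.
#' @export
subset_trials <- function(eeg, idx) {
  eeg$data <- eeg$data[idx, , , drop = FALSE]
  eeg$trial_meta <- eeg$trial_meta[idx, , drop = FALSE]
  eeg
}

#' Persist epoched EEG in an HDF5 container
#'
#' Writes/reads the voltage array, time axis, channel labels, trial metadata
#' and subject attributes to a single HDF5 file, so preprocessed epochs can
#' be cached and re-loaded bit-identically.
#'
#' @param eeg An `epoched_eeg` object.
#' @param path Path of the `.h5` file (overwritten if present).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()`
#'   returns the restored `epoched_eeg`.
#' @export
write_epochs <- function(eeg, path) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(eeg$data, path, "data")
  rhdf5::h5write(eeg$times, path, "times")
  rhdf5::h5write(eeg$channel_labels, path, "channel_labels")
  meta <- as.data.frame(eeg$trial_meta)
  rhdf5::h5write(meta, path, "trial_meta")
  rhdf5::h5write(eeg$sampling_rate, path, "sampling_rate")
  rhdf5::h5write(as.character(eeg$subject_id), path, "subject_id")
  rhdf5::h5write(as.character(eeg$group), path, "group")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  on.exit(rhdf5::h5closeAll())
  meta <- rhdf5::h5read(path, "trial_meta")
  meta[] <- lapply(meta, as.vector)
  epoched_eeg(
    data = rhdf5::h5read(path, "data"),
    sampling_rate = as.numeric(rhdf5::h5read(path, "sampling_rate")),
    times = as.numeric(rhdf5::h5read(path, "times")),
    channel_labels = as.character(rhdf5::h5read(path, "channel_labels")),
    trial_meta = tibble::as_tibble(meta),
    subject_id = as.character(rhdf5::h5read(path, "subject_id")),
    group = as.character(rhdf5::h5read(path, "group"))
  )
}

#' Standard 64-channel montage labels
#'
#' Extended 10-20 labels for the 64 scalp channels used by the simulator,
#' plus optional `EXG1`..`EXG4` eye-channel labels.
#'
#' @param n_channels Number of scalp channels (64 gives the named montage;
#'   other counts get generic `Ch01`.. labels).
#' @param eog Append the four EOG labels?
#' @return Character vector of labels.
#' @export
montage_labels <- function(n_channels = 64, eog = FALSE) {
  m64 <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz", "Fpz",
    "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6",
    "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
    "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
  labels <- if (n_channels == 64) m64 else sprintf("Ch%02d",
                                                   seq_len(n_channels))
  if (eog) labels <- c(labels, sprintf("EXG%d", 1:4))
  labels
}

is_eog_label <- function(labels) grepl("^(EXG|EOG|VEOG|HEOG)", labels)
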