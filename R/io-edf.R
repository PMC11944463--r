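#' Read a continuous EEG recording from EDF or BDF
#'
#' Minimal reader for European Data Format (16-bit) and BioSemi Data
#' Format (24-bit) files: parses the fixed-width ASCII header, reads all
#' data records, applies the per-signal digital-to-physical scaling, and
#' returns a [continuous_eeg()]. All signals must share one sampling rate
#' (true for the recordings this pipeline targets); annotation channels
#' are not supported.
#'
#' @param path Path to a `.edf` or `.bdf` file.
#' @return A [continuous_eeg()] with channel labels from the file header.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  bdf <- magic[1] == as.raw(255)
  fmt_label <- if (bdf) "BDF" else "EDF"
  ascii <- function(nbytes) trimws(rawToChar(readBin(con, "raw", nbytes)))
  ascii(80) # patient id
  ascii(80) # recording id
  ascii(8)  # start date
  ascii(8)  # start time
  header_bytes <- as.integer(ascii(8))
  ascii(44) # reserved
  n_records <- as.integer(ascii(8))
  record_dur <- as.numeric(ascii(8))
  ns <- as.integer(ascii(4))
  if (is.na(ns) || ns < 1) stopf("malformed %s header in %s", fmt_label,
                                 path)
  field <- function(w) vapply(seq_len(ns), function(i) ascii(w),
                              character(1))
  labels <- field(16)
  field(80) # transducer
  field(8)  # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80) # prefiltering
  n_samp <- as.integer(field(8))
  field(32) # reserved
  seek(con, header_bytes)
  if (length(unique(n_samp)) != 1) {
    stopf("signals with differing sampling rates are not supported (%s)",
          path)
  }
  spr <- n_samp[1]
  rate <- spr / record_dur
  data <- matrix(0, ns, n_records * spr)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      dig <- if (bdf) {
        b <- readBin(con, "integer", spr * 3, size = 1, signed = FALSE)
        b <- matrix(b, nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        ifelse(v >= 8388608, v - 16777216, v)
      } else {
        readBin(con, "integer", spr, size = 2, signed = TRUE,
                endian = "little")
      }
      gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
      data[s, ((r - 1) * spr + 1):(r * spr)] <-
        (dig - dig_min[s]) * gain + phys_min[s]
    }
  }
  continuous_eeg(data, rate, labels)
}

# Minimal EDF/BDF writer, used to build test fixtures and round-trip the
# reader; one data-record spans the full signal.
write_edf <- function(data, sampling_rate, channel_labels, path,
                      bdf = FALSE) {
  ns <- nrow(data)
  n_t <- ncol(data)
  phys_min <- floor(apply(data, 1, min)) - 1
  phys_max <- ceiling(apply(data, 1, max)) + 1
  dig_min <- if (bdf) -8388608 else -32768
  dig_max <- if (bdf) 8388607 else 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    out <- formatC(as.character(x), width = -w)
    writeBin(charToRaw(paste(substr(out, 1, w), collapse = "")), con)
  }
  if (bdf) {
    writeBin(as.raw(255), con)
    writeBin(charToRaw(formatC("BIOSEMI", width = -7)), con)
  } else {
    pad("0", 8)
  }
  pad("synthetic", 80)
  pad("synthetic", 80)
  pad("01.01.26", 8)
  pad("00.00.00", 8)
  pad(256 * (ns + 1), 8)
  pad(if (bdf) "24BIT" else "", 44)
  pad(1, 8) # one record
  pad(format(n_t / sampling_rate), 8)
  pad(ns, 4)
  for (l in channel_labels) pad(l, 16)
  for (i in seq_len(ns)) pad("simulated", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (v in phys_min) pad(format(v), 8)
  for (v in phys_max) pad(format(v), 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("none", 80)
  for (i in seq_len(ns)) pad(n_t, 8)
  for (i in seq_len(ns)) pad("", 32)
  for (s in seq_len(ns)) {
    gain <- (phys_max[s] - phys_min[s]) / (dig_max - dig_min)
    dig <- round((data[s, ] - phys_min[s]) / gain + dig_min)
    if (bdf) {
      v <- ifelse(dig < 0, dig + 16777216, dig)
      bytes <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
      writeBin(as.raw(as.vector(bytes)), con)
    } else {
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Load a real dataset from a manifest
#'
#' Reads a TSV manifest with columns `subject_id`, `group`, `file`
#' (EDF/BDF recording) and `events` (TSV sidecar with an `onset_ms`
#' column and optional per-trial metadata such as `emotion` and
#' `morph_condition`), epochs each recording, and returns the list of
#' [epoched_eeg()] objects ready for [run_experiment()]'s `eeg_list`
#' argument. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param epoch_window Epoch limits in ms (default `c(-200, 1000)`).
#' @return List of `epoched_eeg` objects (empty manifest gives an empty
#'   list).
#' @export
load_real_dataset <- function(manifest_path, epoch_window = c(-200, 1000)) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  required <- c("subject_id", "group", "file", "events")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stopf("manifest lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  root <- dirname(manifest_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)
  purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    f <- resolve(row$file)
    if (!file.exists(f)) {
      stopf("manifest row %d: recording not found: %s", i, row$file)
    }
    ev_path <- resolve(row$events)
    if (!file.exists(ev_path)) {
      stopf("manifest row %d: event table not found: %s", i, row$events)
    }
    events <- readr::read_tsv(ev_path, show_col_types = FALSE)
    if (!"onset_ms" %in% names(events)) {
      stopf("manifest row %d: event table lacks 'onset_ms'", i)
    }
    cont <- read_edf(f)
    cont$subject_id <- row$subject_id
    cont$group <- row$group
    meta <- dplyr::select(events, -"onset_ms")
    if (ncol(meta) == 0) meta <- NULL
    segment_epochs(cont, events$onset_ms, epoch_window, trial_meta = meta)
  })
}
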