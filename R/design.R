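#' Build the factorial voice-morph stimulus design
#'
#' Enumerates the full stimulus set of the experiment: every combination of
#' speaker, pseudoword, emotion and morph condition, optionally plus one
#' emotionally uninformative "average" stimulus per speaker/pseudoword pair.
#' Under the defaults (8 speakers, 3 pseudowords, 4 emotions, 3 morph
#' conditions, averages included) this yields 288 emotional + 24 average =
#' 312 stimuli.
#'
#' @param n_speakers Number of speakers (default 8).
#' @param n_words Number of pseudowords (default 3; the first three are
#'   named "molen", "loman", "belam").
#' @param emotions Character vector of emotion labels (default the four
#'   canonical categories).
#' @param morph_conditions Character vector of morph-condition labels
#'   (default `full`, `f0`, `timbre`).
#' @param include_averages Add one `average`/`average` stimulus per
#'   (speaker, pseudoword)? Default `TRUE`.
#' @return A tibble with columns `stimulus_id`, `speaker_id`, `pseudoword`,
#'   `emotion`, `morph_condition`; class `stimulus_design`.
#' @examples
#' design <- build_stimulus_design()
#' nrow(design) # 312
#' @export
build_stimulus_design <- function(n_speakers = 8, n_words = 3,
                                  emotions = emotion_levels,
                                  morph_conditions = morph_levels,
                                  include_averages = TRUE) {
  if (n_speakers < 1 || n_words < 1) {
    stopf("n_speakers and n_words must be >= 1")
  }
  if (length(emotions) == 0 || length(morph_conditions) == 0) {
    stopf("emotions and morph_conditions must be non-empty")
  }
  base_words <- c("molen", "loman", "belam")
  words <- if (n_words <= 3) base_words[seq_len(n_words)] else {
    c(base_words, sprintf("word%02d", seq(4, n_words)))
  }
  design <- tidyr::expand_grid(
    speaker_id = seq_len(n_speakers),
    pseudoword = words,
    emotion = emotions,
    morph_condition = morph_conditions
  )
  if (include_averages) {
    averages <- tidyr::expand_grid(
      speaker_id = seq_len(n_speakers),
      pseudoword = words,
      emotion = "average",
      morph_condition = "average"
    )
    design <- dplyr::bind_rows(design, averages)
  }
  design <- dplyr::mutate(design, stimulus_id = dplyr::row_number(),
                          .before = 1)
  class(design) <- c("stimulus_design", class(design))
  design
}

#' Build a randomized per-subject trial sequence
#'
#' Concatenates `n_reps` independent random orderings of the full stimulus
#' design (the experiment presented all stimuli once in random order, then
#' again in a different random order), partitions the sequence into equally
#' sized consecutive blocks, and flags a fixed fraction of trials as
#' response-prompt trials, sampled without replacement. Prompt trials are
#' retained in all downstream analyses.
#'
#' @param design A `stimulus_design` tibble.
#' @param n_reps Number of random passes through the design (default 2).
#' @param n_blocks Number of blocks (default 8); `n_reps * nrow(design)`
#'   must be divisible by `n_blocks`.
#' @param prompt_rate Fraction of trials with a response prompt
#'   (default 0.10); the prompt count is exactly `round(prompt_rate * N)`.
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A tibble with columns `trial_index`, `stimulus_id`, `block`,
#'   `repetition`, `prompt`; class `trial_table`. Defaults give 624 trials
#'   in 8 blocks of 78 with 62 prompts.
#' @export
build_trial_table <- function(design, n_reps = 2, n_blocks = 8,
                              prompt_rate = 0.10, seed = 1L) {
  n_stim <- nrow(design)
  n_total <- n_reps * n_stim
  if (n_total %% n_blocks != 0) {
    stopf("n_reps * nrow(design) = %d is not divisible by n_blocks = %d",
          n_total, n_blocks)
  }
  withr_seed(seed, {
    order_idx <- unlist(lapply(seq_len(n_reps),
                               function(r) sample.int(n_stim)))
    n_prompt <- round(prompt_rate * n_total)
    prompt_idx <- sample.int(n_total, n_prompt)
  })
  tt <- tibble::tibble(
    trial_index = seq_len(n_total),
    stimulus_id = design$stimulus_id[order_idx],
    block = rep(seq_len(n_blocks), each = n_total / n_blocks),
    repetition = rep(seq_len(n_reps), each = n_stim),
    prompt = seq_len(n_total) %in% prompt_idx
  )
  class(tt) <- c("trial_table", class(tt))
  tt
}

# Evaluate expr under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Build a two-group subject cohort
#'
#' Creates the simulated cohort: musicians and non-musicians with unique
#' subject ids and per-subject seeds derived from the master seed, so adding
#' a subject never perturbs the data of existing subjects.
#'
#' @param n_musicians,n_non_musicians Group sizes (defaults 38 and 39).
#' @param master_seed Integer master seed.
#' @return A tibble with columns `subject_id`, `group`, `seed`;
#'   class `subject_cohort`.
#' @export
build_cohort <- function(n_musicians = 38, n_non_musicians = 39,
                         master_seed = 1L) {
  n <- n_musicians + n_non_musicians
  cohort <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("musician", "non_musician"),
                c(n_musicians, n_non_musicians)),
    seed = vapply(seq_len(n), function(i) child_seed(master_seed, i),
                  integer(1))
  )
  class(cohort) <- c("subject_cohort", class(cohort))
  cohort
}

#' Read/write design tables as TSV
#'
#' Stimulus designs and trial tables round-trip through plain TSV files with
#' a fixed header.
#'
#' @param x A `stimulus_design` or `trial_table` tibble.
#' @param path File path.
#' @return `read_*` return the tibble with its class restored;
#'   `write_*` return `path` invisibly.
#' @name design_io
NULL

#' @rdname design_io
#' @export
write_design_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname design_io
#' @export
read_stimulus_design <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         stimulus_id = "i", speaker_id = "i",
                         pseudoword = "c", emotion = "c",
                         morph_condition = "c"))
  class(x) <- c("stimulus_design", class(x))
  x
}

#' @rdname design_io
#' @export
read_trial_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         trial_index = "i", stimulus_id = "i", block = "i",
                         repetition = "i", prompt = "l"))
  class(x) <- c("trial_table", class(x))
  x
}
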