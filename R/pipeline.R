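#' Experiment configuration
#'
#' Bundles every sub-configuration of an end-to-end run: stimulus design
#' and trial-table parameters, cohort sizes, the simulation, preprocessing
#' and statistics configs, the decoding schemes and the smoothing window.
#' All defaults mirror the study design: 312 stimuli presented twice in 8
#' blocks of 78 trials, 38 musicians + 39 non-musicians, 250/100 Hz
#' resampling, 5-point smoothing, 10000 permutation iterations at alpha
#' 0.05.
#'
#' @param simulation A [simulation_config()].
#' @param preprocess A [preprocess_config()].
#' @param stats A [stat_config()].
#' @param schemes Character vector of scheme names (default all three).
#' @param n_musicians,n_non_musicians Cohort sizes (defaults 38, 39).
#' @param design_args List of arguments to [build_stimulus_design()].
#' @param trial_args List of arguments to [build_trial_table()] (without
#'   `design`/`seed`).
#' @param smoothing_window Rolling-mean window (default 5 timepoints).
#' @param include_baseline Decode baseline timepoints too? Default `FALSE`.
#' @param lambda LDA shrinkage (default 0.01).
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(simulation = simulation_config(),
                              preprocess = preprocess_config(),
                              stats = stat_config(),
                              schemes = c("all_all", "full_to_f0",
                                          "full_to_timbre"),
                              n_musicians = 38, n_non_musicians = 39,
                              design_args = list(), trial_args = list(),
                              smoothing_window = 5,
                              include_baseline = FALSE, lambda = 0.01) {
  structure(list(simulation = simulation, preprocess = preprocess,
                 stats = stats, schemes = schemes,
                 n_musicians = n_musicians,
                 n_non_musicians = n_non_musicians,
                 design_args = design_args, trial_args = trial_args,
                 smoothing_window = smoothing_window,
                 include_baseline = include_baseline, lambda = lambda),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Nested keys `simulation`, `preprocess`, `stats` map onto the
#' corresponding config constructors; scalar keys map onto
#' [experiment_config()] arguments. Unknown keys raise an error.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fun, args) {
    if (is.null(args)) return(fun())
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad) > 0) stopf("unknown config key(s): %s",
                               paste(bad, collapse = ", "))
    if (!is.null(args$effects) && !is.data.frame(args$effects)) {
      args$effects <- dplyr::bind_rows(args$effects)
    }
    do.call(fun, args)
  }
  sim <- build(simulation_config, y$simulation)
  pre <- build(preprocess_config, y$preprocess)
  st <- build(stat_config, y$stats)
  rest <- y[setdiff(names(y), c("simulation", "preprocess", "stats"))]
  bad <- setdiff(names(rest), names(formals(experiment_config)))
  if (length(bad) > 0) stopf("unknown config key(s): %s",
                             paste(bad, collapse = ", "))
  do.call(experiment_config,
          c(list(simulation = sim, preprocess = pre, stats = st), rest))
}

#' Run a full synthetic experiment
#'
#' For every subject of the cohort: build a randomized trial table,
#' simulate the epoched EEG, preprocess it, decode each scheme in a
#' time-resolved manner, and smooth the accuracy timecourse. Then, for
#' each analysis family (across groups, musicians only, non-musicians
#' only) crossed with each scheme, run the TFCE sign-flip permutation
#' test and summarize significant clusters -- the 3 x 3 grid of the
#' study's figures. Fully deterministic under the simulation master seed
#' and the statistics seed.
#'
#' @param config An [experiment_config()].
#' @param output_dir Optional directory; when given, all artifacts
#'   (accuracy TSV, per-analysis map and cluster TSVs, a JSON manifest
#'   with the config hash and seeds) are written there.
#' @param eeg_list Optional pre-built list of [epoched_eeg()] objects
#'   (e.g. from [load_real_dataset()]); skips simulation. Each element
#'   must carry `subject_id` and `group`.
#' @param verbose Print per-subject progress? Default `FALSE`.
#' @return A list of class `experiment_bundle` with elements `curves`
#'   (all smoothed accuracy timecourses), `analyses` (named list of
#'   `cluster_stat_result`, names `<population>.<scheme>`), `summary`
#'   (one tibble of all cluster reports), `config`, `config_hash`.
#' @export
run_experiment <- function(config = experiment_config(),
                           output_dir = NULL, eeg_list = NULL,
                           verbose = FALSE) {
  hash <- digest::digest(config)
  if (is.null(eeg_list)) {
    design <- do.call(build_stimulus_design, config$design_args)
    cohort <- build_cohort(config$n_musicians, config$n_non_musicians,
                           master_seed = config$simulation$master_seed)
    subjects <- seq_len(nrow(cohort))
  } else {
    design <- NULL
    subjects <- seq_along(eeg_list)
  }
  curves <- purrr::map_dfr(subjects, function(i) {
    if (is.null(eeg_list)) {
      subject <- cohort[i, ]
      tt <- do.call(build_trial_table,
                    c(list(design = design,
                           seed = child_seed(subject$seed, 1L)),
                      config$trial_args))
      eeg <- tryCatch(
        simulate_subject_eeg(tt, design, subject, config$simulation),
        error = function(e) stopf("stage 'simulate' failed for %s: %s",
                                  subject$subject_id, conditionMessage(e)))
    } else {
      eeg <- eeg_list[[i]]
    }
    if (verbose) message("subject ", eeg$subject_id)
    pre <- tryCatch(preprocess_eeg(eeg, config$preprocess),
                    error = function(e)
                      stopf("stage 'preprocess' failed for %s: %s",
                            eeg$subject_id, conditionMessage(e)))
    purrr::map_dfr(config$schemes, function(s) {
      tryCatch(
        time_resolved_decode(pre, decoding_scheme(s),
                             include_baseline = config$include_baseline,
                             lambda = config$lambda),
        error = function(e) stopf("stage 'decode/%s' failed for %s: %s",
                                  s, pre$subject_id, conditionMessage(e)))
    })
  })
  curves <- smooth_timecourse(curves, config$smoothing_window)

  populations <- list(across = c("musician", "non_musician"),
                      musician = "musician",
                      non_musician = "non_musician")
  analyses <- list()
  a_idx <- 0L
  for (pop in names(populations)) {
    for (s in config$schemes) {
      a_idx <- a_idx + 1L
      sub <- dplyr::filter(curves, .data$group %in% populations[[pop]],
                           .data$scheme == s)
      if (nrow(sub) == 0 ||
          length(unique(sub$subject_id)) < 2) next
      st <- config$stats
      st$seed <- child_seed(config$stats$seed, a_idx)
      analyses[[paste(pop, s, sep = ".")]] <- permutation_test(sub, st)
    }
  }
  summary <- purrr::imap_dfr(analyses, function(a, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    dplyr::mutate(a$clusters, population = parts[1], scheme = parts[2],
                  .before = 1)
  })
  bundle <- structure(list(curves = curves, analyses = analyses,
                           summary = summary, config = config,
                           config_hash = hash),
                      class = "experiment_bundle")
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_timecourse(bundle$curves, file.path(output_dir, "accuracy.tsv"))
  for (nm in names(bundle$analyses)) {
    write_stat_result(bundle$analyses[[nm]], file.path(output_dir, nm))
  }
  readr::write_tsv(bundle$summary, file.path(output_dir, "clusters.tsv"))
  jsonlite::write_json(
    list(config_hash = bundle$config_hash,
         master_seed = bundle$config$simulation$master_seed,
         stats_seed = bundle$config$stats$seed,
         n_analyses = length(bundle$analyses),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(output_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(output_dir)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d subjects, %d analyses (hash %s)\n",
              length(unique(x$curves$subject_id)), length(x$analyses),
              substr(x$config_hash, 1, 8)))
  for (nm in names(x$analyses)) {
    cl <- x$analyses[[nm]]$clusters
    cat(sprintf("  %-28s %d significant cluster(s)\n", nm, nrow(cl)))
  }
  invisible(x)
}
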