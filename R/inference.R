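#' Statistical configuration for group inference
#'
#' Parameters of the one-tailed TFCE sign-flip permutation test of group
#' decoding accuracy against chance: significance level, permutation count,
#' TFCE extent/height exponents and integration step, and the RNG seed.
#' Family-wise correction across timepoints uses the maximum TFCE statistic
#' of each permutation (Monte Carlo correction); each scheme-by-group
#' analysis is corrected separately.
#'
#' @param alpha Significance level (default 0.05).
#' @param n_iterations Permutation count (default 10000; must be >= 100).
#' @param tfce_e Extent exponent E (default 0.5).
#' @param tfce_h Height exponent H (default 2).
#' @param tfce_dh Threshold integration step in t units (default 0.1).
#' @param chance Chance accuracy (default 0.25 for 4 classes).
#' @param seed Integer RNG seed for the sign flips.
#' @param exhaustive Enumerate all `2^n` sign assignments instead of
#'   sampling (only allowed for n <= 16 subjects)? Default `FALSE`.
#' @param t_cap Finite cap replacing infinite t at zero-variance
#'   timepoints with non-zero mean deviation (default 100, far above any
#'   attainable finite t yet small enough to keep the TFCE threshold sweep
#'   bounded).
#' @return A list of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05, n_iterations = 10000, tfce_e = 0.5,
                        tfce_h = 2, tfce_dh = 0.1, chance = 0.25,
                        seed = 1L, exhaustive = FALSE, t_cap = 100) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (!exhaustive && n_iterations < 100) {
    stopf("n_iterations must be >= 100, got %d", n_iterations)
  }
  if (tfce_dh <= 0) stopf("tfce_dh must be > 0")
  structure(list(alpha = alpha, n_iterations = as.integer(n_iterations),
                 tfce_e = tfce_e, tfce_h = tfce_h, tfce_dh = tfce_dh,
                 chance = chance, seed = as.integer(seed),
                 exhaustive = exhaustive, t_cap = t_cap),
            class = "stat_config")
}

# Accept a subjects x timepoints matrix or a tidy accuracy_timecourse and
# return list(mat, times, subjects).
curves_matrix <- function(curves) {
  if (is.matrix(curves)) {
    times <- as.numeric(colnames(curves) %||% seq_len(ncol(curves)))
    if (anyNA(times)) times <- seq_len(ncol(curves))
    return(list(mat = curves, times = times,
                subjects = rownames(curves) %||%
                  sprintf("S%03d", seq_len(nrow(curves)))))
  }
  wide <- curves |>
    dplyr::select("subject_id", "time_ms", "accuracy") |>
    tidyr::pivot_wider(names_from = "time_ms", values_from = "accuracy")
  mat <- as.matrix(wide[, -1])
  list(mat = mat, times = as.numeric(colnames(mat)),
       subjects = wide$subject_id)
}

#' One-sample t map against chance
#'
#' Per timepoint, the one-sample t statistic of the across-subject
#' accuracy deviations from chance: `t = mean(acc - chance) /
#' (sd / sqrt(n))` with the n-1 denominator in `sd`. At a zero-variance
#' timepoint, t is 0 when the mean deviation is 0 and is otherwise capped
#' at a large finite value (sign preserved) so TFCE integration stays
#' finite.
#'
#' @param curves Subjects x timepoints matrix of accuracies, or a tidy
#'   `accuracy_timecourse` with one curve per subject.
#' @param chance Chance level (default 0.25).
#' @param t_cap Finite replacement for infinite t (default 100).
#' @return Numeric vector of t values, one per timepoint.
#' @export
one_sample_tmap <- function(curves, chance = 0.25, t_cap = 100) {
  cm <- curves_matrix(curves)
  if (nrow(cm$mat) < 2) stopf("need >= 2 subjects, found %d", nrow(cm$mat))
  d <- cm$mat - chance
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  n <- nrow(d)
  t <- m / (s / sqrt(n))
  zero <- s == 0
  t[zero & m == 0] <- 0
  t[zero & m != 0] <- sign(m[zero & m != 0]) * t_cap
  t
}

#' Threshold-free cluster enhancement of a 1-d statistic map
#'
#' For each timepoint p, integrates cluster support over all thresholds:
#' `tfce(p) = sum over h in {dh, 2dh, ..., max(map)} of
#' e(p, h)^E * h^H * dh`, where `e(p, h)` is the length in timepoints of
#' the contiguous suprathreshold run (`map >= h`) containing p. Only the
#' positive tail is enhanced: negative values contribute nothing, matching
#' the one-tailed test for above-chance decoding.
#'
#' @param stat_map Finite numeric vector (e.g. a t map).
#' @param e,h Extent and height exponents (defaults 0.5 and 2).
#' @param dh Threshold step (default 0.1).
#' @return Numeric vector of TFCE scores, same length as `stat_map`.
#' @export
tfce_1d <- function(stat_map, e = 0.5, h = 2, dh = 0.1) {
  if (any(!is.finite(stat_map))) {
    stopf("stat_map must be finite; found non-finite values")
  }
  as.numeric(cpp_tfce_1d(as.numeric(stat_map), e, h, dh))
}

#' One-tailed TFCE sign-flip permutation test against chance
#'
#' Tests whether group-mean decoding accuracy exceeds chance anywhere in
#' the epoch, with family-wise control across timepoints. The observed
#' statistic is the TFCE-enhanced one-sample t map of the accuracy
#' deviations. Under the null each subject's whole deviation curve is
#' sign-symmetric, so the null distribution is built by randomly flipping
#' the sign of each subject's curve, recomputing the TFCE map, and
#' recording its maximum; `p_corrected(t) = (1 + #\{null max >= observed
#' tfce(t)\}) / (n_iterations + 1)`. With `exhaustive = TRUE` all `2^n`
#' sign assignments are enumerated and the p value is exact.
#'
#' @param curves Subjects x timepoints accuracy matrix, or a tidy
#'   `accuracy_timecourse` (smoothed curves on a common grid).
#' @param config A [stat_config()].
#' @return An object of class `cluster_stat_result`: a list with `times`,
#'   `group_mean_accuracy`, `t_map`, `tfce_map`, `p_corrected`,
#'   `sig_mask`, `clusters` (see [summarize_clusters()]), `config`,
#'   `n_subjects`.
#' @export
permutation_test <- function(curves, config = stat_config()) {
  cm <- curves_matrix(curves)
  n <- nrow(cm$mat)
  if (n < 2) stopf("need >= 2 subjects, found %d", n)
  d <- cm$mat - config$chance
  t_obs <- one_sample_tmap(cm$mat, config$chance, config$t_cap)
  tfce_obs <- tfce_1d(t_obs, config$tfce_e, config$tfce_h, config$tfce_dh)
  if (config$exhaustive) {
    if (n > 16) stopf("exhaustive mode supports at most 16 subjects")
    null_max <- as.numeric(cpp_perm_null_max_exhaustive(
      d, config$tfce_e, config$tfce_h, config$tfce_dh, config$t_cap))
    p <- vapply(tfce_obs, function(v) mean(null_max >= v - 1e-12),
                numeric(1))
  } else {
    null_max <- as.numeric(withr_seed(config$seed, {
      cpp_perm_null_max(d, config$n_iterations, config$tfce_e,
                        config$tfce_h, config$tfce_dh, config$t_cap)
    }))
    p <- vapply(tfce_obs, function(v) {
      (1 + sum(null_max >= v - 1e-12)) / (config$n_iterations + 1)
    }, numeric(1))
  }
  res <- structure(list(
    times = cm$times,
    group_mean_accuracy = colMeans(cm$mat),
    t_map = t_obs, tfce_map = tfce_obs, p_corrected = p,
    sig_mask = p <= config$alpha,
    config = config, n_subjects = n), class = "cluster_stat_result")
  res$clusters <- summarize_clusters(res)
  res
}

#' Summarize significant clusters
#'
#' Reports each maximal run of significant timepoints as one row: start
#' and end time, peak group-mean accuracy inside the run (as percent), and
#' the minimal corrected p value -- the format in which time-resolved
#' decoding results are conventionally reported.
#'
#' @param result A `cluster_stat_result`.
#' @return A tibble with columns `start_ms`, `end_ms`, `peak_accuracy_pct`,
#'   `min_p`; zero rows when nothing is significant.
#' @export
summarize_clusters <- function(result) {
  mask <- result$sig_mask
  if (!any(mask)) {
    return(tibble::tibble(start_ms = numeric(), end_ms = numeric(),
                          peak_accuracy_pct = numeric(),
                          min_p = numeric()))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  purrr::map_dfr(keep, function(k) {
    i <- starts[k]:ends[k]
    tibble::tibble(
      start_ms = result$times[starts[k]],
      end_ms = result$times[ends[k]],
      peak_accuracy_pct = 100 * max(result$group_mean_accuracy[i]),
      min_p = min(result$p_corrected[i]))
  })
}

#' @export
print.cluster_stat_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_stat_result> %d subjects, %d timepoints, alpha = %g\n",
    x$n_subjects, length(x$times), x$config$alpha))
  if (nrow(x$clusters) == 0) {
    cat("  no significant clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf(
        "  %g-%g ms (peak accuracy = %.1f%%, p %s)\n",
        x$clusters$start_ms[i], x$clusters$end_ms[i],
        x$clusters$peak_accuracy_pct[i],
        format_p(x$clusters$min_p[i])))
    }
  }
  invisible(x)
}

format_p <- function(p) {
  if (p < 0.001) "< 0.001" else sprintf("= %.3f", p)
}

#' Write a cluster-stat result to TSV + JSON
#'
#' Persists the per-timepoint maps and the per-cluster summary as two TSV
#' files, plus a JSON echo of the statistical configuration for
#' provenance.
#'
#' @param result A `cluster_stat_result`.
#' @param prefix Path prefix; writes `<prefix>_map.tsv`,
#'   `<prefix>_clusters.tsv`, `<prefix>_config.json`.
#' @return The three paths, invisibly.
#' @export
write_stat_result <- function(result, prefix) {
  map_path <- paste0(prefix, "_map.tsv")
  cl_path <- paste0(prefix, "_clusters.tsv")
  cfg_path <- paste0(prefix, "_config.json")
  readr::write_tsv(tibble::tibble(
    time_ms = result$times,
    group_mean_accuracy = result$group_mean_accuracy,
    t = result$t_map, tfce = result$tfce_map,
    p_corrected = result$p_corrected,
    significant = result$sig_mask), map_path)
  readr::write_tsv(result$clusters, cl_path)
  jsonlite::write_json(
    c(unclass(result$config), list(n_subjects = result$n_subjects)),
    cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(c(map_path, cl_path, cfg_path))
}
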