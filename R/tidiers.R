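#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster-stat result
#'
#' One row per timepoint with the group-mean accuracy, t statistic, TFCE
#' score, corrected p value and significance flag.
#'
#' @param x A `cluster_stat_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cluster_stat_result <- function(x, ...) {
  tibble::tibble(time_ms = x$times,
                 group_mean_accuracy = x$group_mean_accuracy,
                 t = x$t_map, tfce = x$tfce_map,
                 p_corrected = x$p_corrected,
                 significant = x$sig_mask)
}

#' Glance at a cluster-stat result
#'
#' @param x A `cluster_stat_result`.
#' @param ... Unused.
#' @return A one-row tibble with the test's headline numbers.
#' @export
glance.cluster_stat_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_timepoints = length(x$times),
                 n_significant = sum(x$sig_mask),
                 n_clusters = nrow(x$clusters),
                 min_p = min(x$p_corrected),
                 peak_accuracy = max(x$group_mean_accuracy),
                 alpha = x$config$alpha,
                 n_iterations = if (x$config$exhaustive) {
                   2L^x$n_subjects
                 } else {
                   x$config$n_iterations
                 })
}

#' Tidy an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return A tibble with one row per class: label, prior, and the class
#'   mean of each feature in list-column `mean`.
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(class = x$class_labels, prior = x$priors,
                 mean = lapply(seq_along(x$class_labels),
                               function(i) x$class_means[i, ]))
}

#' Glance at an LDA model
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$class_labels),
                 n_features = ncol(x$class_means),
                 shrinkage = x$shrinkage)
}
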