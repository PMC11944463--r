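#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot accuracy timecourses
#'
#' Accuracy against time with the 0.25 chance line; multiple subjects are
#' drawn as thin lines behind the across-subject mean.
#'
#' @param object An `accuracy_timecourse` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accuracy_timecourse <- function(object, ...) {
  mean_tc <- object |>
    dplyr::group_by(.data$scheme, .data$time_ms) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_ms,
                                    y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = mean_tc, colour = "#2166ac",
                       linewidth = 0.9) +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy") +
    ggplot2::theme_minimal()
  if (length(unique(object$scheme)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$scheme))
  }
  p
}

#' Plot a cluster-stat result
#'
#' Group-mean accuracy over time with the chance line, an across-subject
#' confidence band is not available from the result alone, and dots above
#' the curve marking significant timepoints.
#'
#' @param object A `cluster_stat_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_stat_result <- function(object, ...) {
  df <- tidy(object)
  dot_y <- max(df$group_mean_accuracy) + 0.01
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms,
                                        y = .data$group_mean_accuracy)) +
    ggplot2::geom_hline(yintercept = object$config$chance,
                        linetype = "dotted") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy") +
    ggplot2::theme_minimal()
  sig <- df[df$significant, ]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(data = sig, y = dot_y, size = 0.8)
  }
  p
}

#' Render the figure grid of an experiment bundle
#'
#' One panel per analysis (population x scheme): across-subject mean
#' accuracy with a 95% confidence band, the dotted chance line at 0.25,
#' and dots marking timepoints significant after TFCE permutation
#' correction. Optionally writes vector (PDF) and raster (PNG) files.
#'
#' @param bundle An `experiment_bundle` from [run_experiment()].
#' @param output_dir Optional directory for `decoding_results.pdf` and
#'   `decoding_results.png`.
#' @return The ggplot object, invisibly when files are written.
#' @export
plot_results <- function(bundle, output_dir = NULL) {
  band <- bundle$curves |>
    dplyr::group_by(.data$group, .data$scheme, .data$time_ms) |>
    dplyr::summarise(mean_acc = mean(.data$accuracy),
                     se = sd(.data$accuracy) /
                       sqrt(dplyr::n()), .groups = "drop")
  panels <- purrr::imap_dfr(bundle$analyses, function(a, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tibble::tibble(population = parts[1], scheme = parts[2],
                   time_ms = a$times,
                   mean_acc = a$group_mean_accuracy,
                   significant = a$sig_mask)
  })
  band_all <- purrr::imap_dfr(bundle$analyses, function(a, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    pops <- switch(parts[1], across = c("musician", "non_musician"),
                   parts[1])
    bundle$curves |>
      dplyr::filter(.data$group %in% pops, .data$scheme == parts[2]) |>
      dplyr::group_by(.data$time_ms) |>
      dplyr::summarise(mean_acc = mean(.data$accuracy),
                       se = sd(.data$accuracy) / sqrt(dplyr::n()),
                       .groups = "drop") |>
      dplyr::mutate(population = parts[1], scheme = parts[2])
  })
  dot_y <- max(panels$mean_acc) + 0.015
  sig <- panels[panels$significant, ]
  p <- ggplot2::ggplot(panels, ggplot2::aes(x = .data$time_ms,
                                            y = .data$mean_acc)) +
    ggplot2::geom_ribbon(
      data = band_all,
      ggplot2::aes(ymin = .data$mean_acc - 1.96 * .data$se,
                   ymax = .data$mean_acc + 1.96 * .data$se),
      fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dotted") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.7) +
    ggplot2::facet_grid(ggplot2::vars(.data$scheme),
                        ggplot2::vars(.data$population)) +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy") +
    ggplot2::theme_minimal()
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_point(data = sig, y = dot_y, size = 0.6)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    ggplot2::ggsave(file.path(output_dir, "decoding_results.pdf"), p,
                    width = 9, height = 7)
    ggplot2::ggsave(file.path(output_dir, "decoding_results.png"), p,
                    width = 9, height = 7, dpi = 150)
    return(invisible(p))
  }
  p
}
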