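#' Train a shrinkage linear discriminant classifier
#'
#' Gaussian equal-covariance LDA with diagonal ("ridge") shrinkage of the
#' pooled within-class covariance: `Sigma_reg = Sigma + lambda *
#' mean(diag(Sigma)) * I`, with default `lambda = 0.01`. The shrinkage
#' guarantees invertibility even with more features than trials per class,
#' which is routine with 64 channels and single-timepoint features. Class
#' priors are empirical.
#'
#' @param x Numeric matrix, trials x features.
#' @param y Class labels (character or factor), one per row of `x`.
#' @param lambda Shrinkage intensity (default 0.01).
#' @param class_order Optional label order; defaults to order of first
#'   appearance of the sorted unique labels of `y`, or the canonical
#'   emotion order when all labels are emotions. Earlier classes win
#'   prediction ties.
#' @return An object of class `lda_model` with elements `class_labels`,
#'   `class_means`, `pooled_covariance` (after shrinkage), `shrinkage`,
#'   `priors`.
#' @export
train_lda <- function(x, y, lambda = 0.01, class_order = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  labels <- class_order %||% {
    u <- unique(y)
    if (all(u %in% emotion_levels)) emotion_levels[emotion_levels %in% u]
    else sort(u)
  }
  labels <- labels[labels %in% y]
  if (length(labels) < 2) stopf("need >= 2 classes, found %d",
                                length(labels))
  counts <- table(factor(y, levels = labels))
  if (any(counts < 2)) {
    stopf("class '%s' has %d trial(s); >= 2 required per class",
          names(counts)[which(counts < 2)[1]], min(counts))
  }
  n <- nrow(x)
  p <- ncol(x)
  k <- length(labels)
  means <- matrix(0, k, p, dimnames = list(labels, colnames(x)))
  scatter <- matrix(0, p, p)
  for (j in seq_len(k)) {
    xi <- x[y == labels[j], , drop = FALSE]
    means[j, ] <- colMeans(xi)
    xc <- sweep(xi, 2, means[j, ])
    scatter <- scatter + crossprod(xc)
  }
  sigma <- scatter / (n - k)
  # unit scale keeps the ridge invertible when the scatter is exactly zero
  scale <- mean(diag(sigma))
  if (scale <= 0) scale <- 1
  sigma_reg <- sigma + lambda * scale * diag(p)
  structure(list(class_labels = labels, class_means = means,
                 pooled_covariance = sigma_reg, shrinkage = lambda,
                 priors = as.numeric(counts) / n),
            class = "lda_model")
}

#' Predict class labels with a trained LDA model
#'
#' Applies the Gaussian equal-covariance rule: for each row the predicted
#' class maximizes `log(prior) - 0.5 * Mahalanobis^2` under the shrunk
#' pooled covariance. Ties are broken deterministically in favour of the
#' earlier class in `model$class_labels`.
#'
#' @param model An `lda_model` from [train_lda()].
#' @param x Numeric matrix, trials x features (same feature dimension as
#'   training).
#' @return Character vector of predicted labels.
#' @export
predict_lda <- function(model, x) {
  x <- as.matrix(x)
  p <- ncol(model$class_means)
  if (ncol(x) != p) {
    stopf("feature dimension %d does not match model dimension %d",
          ncol(x), p)
  }
  ch <- chol(model$pooled_covariance)
  # discriminant: log prior - 0.5 * (x - mu)' Sigma^-1 (x - mu)
  scores <- vapply(seq_along(model$class_labels), function(j) {
    d <- sweep(x, 2, model$class_means[j, ])
    z <- backsolve(ch, t(d), transpose = TRUE)
    log(model$priors[j]) - 0.5 * colSums(z^2)
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  # max.col with ties.method = "first" implements the documented tie-break
  model$class_labels[max.col(scores, ties.method = "first")]
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  predict_lda(object, newdata)
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes (%s), %d features, lambda = %g\n",
              length(x$class_labels),
              paste(x$class_labels, collapse = ", "),
              ncol(x$class_means), x$shrinkage))
  invisible(x)
}
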