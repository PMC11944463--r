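# Small shared fixtures, all generated in code.

# 2 speakers x 2 words: 48 emotional + 4 average = 52 stimuli,
# 104 trials over 2 blocks -- the "desk-scale" version of the design.
small_design <- function() build_stimulus_design(n_speakers = 2, n_words = 2)

small_trials <- function(design = small_design(), seed = 5L) {
  build_trial_table(design, n_reps = 2, n_blocks = 2, seed = seed)
}

musician_subject <- function(seed = 11L) {
  tibble::tibble(subject_id = "S001", group = "musician", seed = seed)
}

non_musician_subject <- function(seed = 12L) {
  tibble::tibble(subject_id = "S002", group = "non_musician", seed = seed)
}

# Simulated + preprocessed musician subject under the default config.
small_preprocessed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      eeg <- simulate_subject_eeg(small_trials(), small_design(),
                                  musician_subject(),
                                  simulation_config(master_seed = 3))
      cache <<- preprocess_eeg(eeg)
    }
    cache
  }
})

# Noise-only epochs with unstructured labels (no class effect anywhere).
null_eeg <- function(n_trials = 96, n_channels = 16, n_time = 12,
                     rate = 100, seed = 21L) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_channels * n_time),
                dim = c(n_trials, n_channels, n_time))
  meta <- tibble::tibble(
    trial_index = seq_len(n_trials),
    emotion = rep(emotion_levels, length.out = n_trials),
    morph_condition = rep(rep(morph_levels, each = 4),
                          length.out = n_trials))
  epoched_eeg(data, rate, (seq_len(n_time) - 1) * 1000 / rate,
              sprintf("Ch%02d", seq_len(n_channels)), meta,
              subject_id = "N001", group = "musician")
}

# Independent brute-force TFCE: explicit threshold summation.
tfce_oracle <- function(map, e = 0.5, h = 2, dh = 0.1) {
  n <- length(map)
  out <- numeric(n)
  mx <- max(map)
  if (mx <= 0) return(out)
  for (hh in dh * seq_len(floor(mx / dh + 1e-12))) {
    supra <- map >= hh
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      out[starts[k]:ends[k]] <- out[starts[k]:ends[k]] +
        r$lengths[k]^e * hh^h * dh
    }
  }
  out
}

# Independent one-sample t map of deviations (rows = subjects).
tmap_oracle <- function(d) {
  apply(d, 2, function(col) mean(col) / (sd(col) / sqrt(length(col))))
}

# Exhaustive sign-flip enumeration: corrected p per timepoint.
perm_oracle_p <- function(mat, chance = 0.25, e = 0.5, h = 2, dh = 0.1) {
  d <- mat - chance
  n <- nrow(d)
  obs <- tfce_oracle(tmap_oracle(d), e, h, dh)
  maxima <- vapply(0:(2^n - 1), function(code) {
    signs <- ifelse(bitwAnd(code, 2^(seq_len(n) - 1)) > 0, -1, 1)
    max(tfce_oracle(tmap_oracle(d * signs), e, h, dh))
  }, numeric(1))
  vapply(obs, function(v) mean(maxima >= v - 1e-12), numeric(1))
}

# Brute-force shrinkage-LDA prediction: argmax over classes of
# log(prior) - 0.5 * Mahalanobis^2 under the shrunk pooled covariance.
lda_oracle_predict <- function(xtrain, ytrain, xtest, lambda = 0.01,
                               labels = sort(unique(ytrain))) {
  n <- nrow(xtrain)
  p <- ncol(xtrain)
  k <- length(labels)
  means <- t(sapply(labels, function(l) {
    colMeans(xtrain[ytrain == l, , drop = FALSE])
  }))
  scatter <- matrix(0, p, p)
  for (l in labels) {
    xc <- sweep(xtrain[ytrain == l, , drop = FALSE], 2,
                means[match(l, labels), ])
    scatter <- scatter + t(xc) %*% xc
  }
  sigma <- scatter / (n - k)
  sigma <- sigma + lambda * mean(diag(sigma)) * diag(p)
  sinv <- solve(sigma)
  priors <- as.numeric(table(factor(ytrain, levels = labels))) / n
  apply(xtest, 1, function(x) {
    scores <- vapply(seq_len(k), function(j) {
      dlt <- x - means[j, ]
      log(priors[j]) - 0.5 * drop(t(dlt) %*% sinv %*% dlt)
    }, numeric(1))
    labels[which.max(scores)]
  })
}
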