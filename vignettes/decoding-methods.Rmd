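---
title: "Time-resolved decoding of vocal emotions from EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved decoding of vocal emotions from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Listeners recognize vocal emotions from two broad acoustic carriers: the
fundamental-frequency contour (F0, the pitch trajectory) and timbre
(formants, spectral level, aperiodicity). Parameter-specific voice
morphing can isolate each carrier: a *full morph* keeps all emotional
parameters, an *F0 morph* keeps only the emotional pitch contour, and a
*timbre morph* keeps only the emotional voice quality, everything else
being taken from an emotionally uninformative average voice. If a
classifier can read the emotion category out of the listener's EEG, and
can do so even when it was trained on full morphs and tested on F0 (or
timbre) morphs, the corresponding acoustic carrier must drive a shared
neural representation.

`emodecode` implements that analysis end to end: a synthetic generator
for epoched 64-channel EEG with the factorial stimulus design of such an
experiment, the minimal no-filter preprocessing chain, per-timepoint
four-class shrinkage LDA under leave-one-trial-out and cross-morph
schemes, and group inference by threshold-free cluster enhancement
(TFCE) with sign-flip permutation. Everything is exercisable without any
real recording; real EDF/BDF data can be routed through the identical
pipeline.

## The stimulus world

The design is fully factorial: 8 speakers x 3 pseudowords x 4 emotions
(happiness, pleasure, fear, sadness) x 3 morph conditions, plus one
emotional-average stimulus per speaker/pseudoword — 288 + 24 = 312
stimuli. A session presents the whole set once in random order and then
again in a different random order (624 trials), cut into 8 blocks of 78.
Ten percent of trials carry a response prompt; the count is implemented
as exactly `round(0.10 * N)` drawn without replacement, which keeps the
invariant deterministic (a per-trial Bernoulli draw would only match the
rate in expectation). Prompt trials stay in the analysis. Average
stimuli carry the emotion label `average` and are excluded from 4-class
decoding, whose chance level is therefore always 0.25.

## The synthetic EEG generator

Each trial's epoch (−200..1000 ms at 500 Hz) is

* spatially correlated 1/f^alpha background noise (`pink_noise_sd`,
  default 10 uV per channel; `pink_alpha = 1`; `channel_mixing = 0.3`
  of the pink variance shared across channels),
* white sensor noise (`white_noise_sd`, default 2 uV),
* plus, for trials whose (group, morph condition) matches an effect
  entry and whose emotion is real, an additive class signal
  `amplitude * topography(emotion) * envelope(t)`.

Per-emotion topographies are drawn once per configuration from a seeded
standard normal over channels — exchangeable, reproducible, and free of
anatomical claims. All default effect entries share one topography
seed, so the scalp patterns are identical across morph conditions;
this is precisely the assumption that makes a classifier trained on
full morphs transfer to F0 morphs. The default effect table gives the
*musician* group an effect in full and F0 conditions between 500 and
900 ms, a zero-amplitude timbre entry, and nothing for non-musicians —
the qualitative pattern the analysis should recover. The envelope is
rectangular by default (raised-cosine ramps are available); no waveform
is claimed beyond "present in the window".

**Why amplitude 2.5 uV.** After average referencing removes the shared
noise component, the per-channel noise floor is about 9 uV. Two emotion
topographies differ per channel by `amplitude * sqrt(2)` on average, so
the pairwise between-class Mahalanobis separation across 64 channels is
roughly `amplitude * sqrt(2 * 64) / 9 = 1.26 * amplitude`. The default
2.5 uV (d around 3) was fixed from this calculation — before any test
was run — so that a single simulated subject decodes clearly above
chance inside the window. The synthetic world therefore validates the
*localization and condition-specificity* of the method, not the
near-chance effect sizes of real EEG; a green recovery test says the
pipeline finds a strong effect where it was injected and nowhere else,
and says nothing about sensitivity at realistic signal-to-noise ratios.

What the generator does *not* emulate: eye/muscle artifacts, electrode
drift and bad channels, event-related spectral perturbations,
inter-subject topographic variability (all subjects share the effect
topographies), and any stimulus-acoustics-driven component. EOG
channels are appended as pure noise only so the removal step is
testable.

Seeds are hierarchical: a master seed derives per-subject streams, so
adding a subject never perturbs another subject's data; permutation
inference is seeded separately per analysis.

## Preprocessing

The chain deliberately mirrors a minimal, no-filter pipeline: resample
to 250 Hz, average reference, (epoch segmentation for continuous
input), removal of the four EOG channels, baseline correction over
−200..0 ms, and a final resample to 100 Hz, yielding 64 channels x 120
samples on the −200, −190, ..., 990 ms grid (left-aligned 10 ms bins;
baseline = samples with t < 0). No frequency filtering, no artifact or
channel rejection, no interpolation: the classifier is left to handle
noisy trials and channels.

**Resampling.** Each epoch/channel is detrended with the line through
its first and last samples, the residual is resampled by a
rational-factor polyphase FIR interpolator, and the trend is evaluated
at the new timepoints and added back, so constants, offsets and exact
linear drifts pass through unchanged. The anti-alias kernel is a
Kaiser-windowed sinc (beta = 8.6, about 60 dB stopband, half-length 20
taps per unit resampling factor) with cutoff at the lower Nyquist
frequency. Two properties drove this design, both visible in the test
suite: pass-band amplitudes are preserved to well under 1%, and a sharp
transient leaks only a few tens of milliseconds. An earlier circular
FFT (spectrum-truncation) implementation was rejected because its
wrap-around and slowly decaying ideal-sinc tails smeared measurable
class signal far outside an injected effect window.

Average referencing excludes EOG channels from the mean and leaves them
untouched. Average reference and baseline correction are linear and
timepoint-/trial-local respectively, hence commute — asserted to 1e−9
in the tests. For continuous input, referencing is applied before
epoching; the reference is timepoint-local, so the order is immaterial
and is fixed only for reproducibility.

## Decoding

Features at a timepoint are the 64 channel voltages of that single
100 Hz sample — at 100 Hz one sample *is* one 10 ms bin, so no further
within-window averaging is applied. The classifier is Gaussian
equal-covariance LDA with ridge shrinkage of the pooled within-class
covariance, `Sigma + lambda * mean(diag(Sigma)) * I`, `lambda = 0.01`:
with 64 features and few trials per fold the unshrunk covariance would
be ill-conditioned or singular. If the scatter is exactly zero
(degenerate input) the ridge scale falls back to 1 so the rule reduces
to nearest-class-mean. Priors are empirical; prediction maximizes
`log(prior) − 0.5 * Mahalanobis^2`; ties resolve to the earlier class
in the canonical order (happiness, pleasure, fear, sadness).

Schemes:

* `all_all` — train and test on all emotional trials,
  leave-one-trial-out: n folds, each trial tested once, accuracy =
  mean of the 0/1 fold outcomes.
* `full_to_f0`, `full_to_timbre` — train once on all full-morph
  trials, test on every F0 (timbre) trial. Because train and test sets
  are disjoint by construction, no fold structure is needed; whether
  the original analysis kept a leave-one-out structure on its training
  set is not stated anywhere, so the simpler disjoint reading is
  implemented and flagged here.

The leave-one-out inner loop is compiled (rank-one downdates of the
class sums and scatter per fold); a pure-R path through `train_lda()` /
`predict_lda()` implements the identical rule and the tests assert
exact agreement between the two and a brute-force Mahalanobis oracle.

Accuracy timecourses cover every post-onset timepoint (baseline
decoding is available as a diagnostic) and are smoothed for inference
by a 5-point centered rolling mean truncated at the epoch edges
(window 5 at 100 Hz = 50 ms).

## Group inference

Per timepoint the statistic is the one-sample t of the subject
accuracy deviations from 0.25 (the timepoint-level statistic is not
named in the source analysis; the one-sample t against chance is the
standard choice for this design). Zero-variance timepoints get t = 0
when the mean deviation is zero, otherwise a finite cap (default 100)
that preserves the sign while keeping the TFCE threshold sweep
bounded.

TFCE integrates cluster support over all thresholds,
`tfce(p) = sum_h e(p, h)^E * h^H * dh` with the canonical E = 0.5,
H = 2, dh = 0.1 (none are stated in the source), over the positive
tail only — only above-chance decoding is meaningful. The null
distribution flips the sign of whole subject curves (the one-sample
permutation null; the source's "bootstrapped distribution" wording is
read as this standard sign-flip scheme and flagged), recomputes the
TFCE map, and keeps its maximum across timepoints; family-wise
corrected p values are `(1 + #{null max >= tfce(p)}) / (n_iter + 1)`,
so p can never fall below `1/(n_iter + 1)`. For n <= 16 subjects an
exhaustive mode enumerates all 2^n assignments and is exact; the test
suite checks it against an independent enumeration oracle and checks
the Monte Carlo mode's family-wise error rate on null cohorts. Each
population-by-scheme analysis is corrected separately, matching how
such results are reported; no correction is applied across the 3 x 3
grid of analyses.

A note on interpretation: with a strong effect, TFCE deliberately lets
a tall cluster raise the score of weakly positive neighboring
timepoints (that is its purpose — no fixed cluster-forming threshold).
Significant timepoints can therefore extend a few samples beyond a
sharply bounded effect, in addition to the +-20 ms spread of the
smoothing window. The recovery tests pool several simulated cohorts
and require 90% of significant timepoints inside the injected window,
which accommodates exactly this bleed. In cluster summaries we treat a
single isolated significant timepoint as an isolated point, not a
cluster; runs of two or more count as clusters.

## The experiment orchestrator

`run_experiment()` composes the whole pipeline per subject and then
runs the 3 x 3 grid of analyses ({across groups, musicians,
non-musicians} x {all_all, full_to_f0, full_to_timbre}), writing
accuracy TSVs, per-analysis map and cluster TSVs, and a manifest with
the config hash and seeds; identical configurations produce
byte-identical outputs. `plot_results()` renders the accuracy curves
with the 0.25 chance line, 95% confidence bands and significance dots.
Real recordings enter through `read_edf()` (EDF and BDF) plus a
TSV manifest and are routed through the identical pipeline.

## Numerical and degenerate-input choices

* Resampler: endpoint-bridge detrend + Kaiser polyphase FIR (above);
  upsampling is refused.
* LDA: ridge `lambda = 0.01` scaled by the mean diagonal variance, with
  a unit fallback scale for exactly zero scatter; ties by canonical
  class order.
* t map: n−1 denominator; zero-variance cap 100.
* Permutation p: add-one formula; observed-vs-null comparisons use a
  1e−12 slack so bitwise-equal statistics compare as ties.
* Baseline window is half-open `[−200, 0)`; effect windows are
  half-open `[start, end)`.
* An empty significance mask yields an empty (zero-row) cluster table,
  not an error.

## Limitations

* The generator's effect model is additive, topographically fixed
  across subjects, and time-locked; real vocal-emotion EEG effects are
  weaker, variable across subjects, and partly oscillatory.
* Accuracy curves are treated as exchangeable across subjects under
  the null; trial-level dependencies (blocks, stimulus repetitions)
  are not modeled in the inference.
* Only one-sample tests against chance are provided; a direct
  two-sample musicians-vs-non-musicians contrast is out of scope.
* The cross-morph schemes assume the training condition's class
  topographies transfer; the generator makes this exactly true, real
  data need not.
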