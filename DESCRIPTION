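Package: emodecode
Title: Time-Resolved EEG Decoding of Vocal Emotions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for time-resolved multivariate
    decoding of vocal emotion categories from epoched scalp EEG. Generates
    synthetic 64-channel epochs with a factorial voice-morphing stimulus
    design (emotion x morph condition), reproduces a minimal no-filter
    preprocessing chain (resampling, average reference, baseline correction),
    performs per-timepoint four-class shrinkage linear discriminant analysis
    under leave-one-trial-out and cross-morph generalization schemes, and
    tests group accuracy timecourses against chance with threshold-free
    cluster enhancement and sign-flip permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    digest,
    rhdf5,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
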