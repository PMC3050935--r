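Package: ethohmm
Title: Hidden Markov Modelling of Minute-Sampled Behavioral Ethograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to segment minute-sampled ethogram observation sequences
    into latent behavioral states with discrete-emission hidden Markov
    models. Provides scaled forward-backward likelihoods, multi-sequence
    Baum-Welch training, Viterbi labeling, BIC-based model selection with
    merged-state alternatives, random-restart robustness sweeps with
    emission-profile state matching, and group comparison of state
    frequencies, compositions, bout durations and transition rates using
    t tests, pooled two-proportion z tests and Benjamini-Hochberg false
    discovery rate control. Includes a synthetic-study generator that
    emulates a multi-strain rodent maternal-behavior observation design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
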