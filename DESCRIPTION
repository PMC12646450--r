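Package: sleepeeg
Title: Quantitative Sleep-EEG Analysis: Hypnogram Architecture, Spectral
    Power, Complexity and Phase-Based Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for polysomnographic sleep studies with
    paired (within-subject) designs. Quantifies sleep architecture from
    scored hypnograms (state percentages, censored latencies,
    transition-probability matrices, Lempel-Ziv complexity of the state
    sequence), computes relative power spectral density and
    magnitude-squared coherence by Welch's method, nonlinear signal
    metrics (median-binarized Lempel-Ziv complexity and Bandt-Pompe
    permutation entropy on low- and high-frequency components), and
    narrowband phase-lag-index connectivity with a phase-randomized
    surrogate significance threshold. Includes nonparametric group
    comparisons (Wilcoxon, Mann-Whitney, Kruskal-Wallis with Dunn
    post-hoc tests) and a synthetic-cohort generator producing
    state-dependent, optionally phase-coupled multichannel EEG with
    Markov hypnograms, so the full pipeline is testable end to end
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
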