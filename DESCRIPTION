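Package: phasemeta
Title: Phase-Locking Metastability Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("phasemeta", "developers", email = "phasemeta@example.org", role = c("aut", "cre"))
Description: Dynamic functional-connectivity analysis of parcellated fMRI-like
    signals through instantaneous phase-locking. Implements leading eigenvector
    dynamics analysis (LEiDA) with spherical k-means mode extraction, the
    conventional Kuramoto metastability (META) together with a phase-locking
    variance proxy (VAR), chimerality, magnetization, graph integration and
    segregation indices, a non-parametric statistical layer (ICC(1,1), aligned
    rank transform factorial ANOVA, Friedman/Wilcoxon, permutation Welch
    t-tests), single-feature naive-Bayes classification, and a generalized
    Haken-Kelso-Bunz coupled-oscillator simulator that produces two-cohort
    synthetic datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
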