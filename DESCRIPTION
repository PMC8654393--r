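Package: cmcdcm
Title: Canonical Microcircuit Dynamic Causal Modelling of EEG Paradigms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Neural mass modelling of cortical columns with the canonical
    microcircuit (four populations: spiny stellate, superficial pyramidal,
    inhibitory interneurons, deep pyramidal), spectral and evoked-response
    forward models for three EEG paradigms (resting EEG, mismatch negativity,
    40-Hz auditory steady-state response), variational Laplace inversion,
    and hierarchical group inference with parametric empirical Bayes,
    Bayesian model reduction and random-effects Bayesian model selection.
    Includes a synthetic-cohort generator for end-to-end testing of the
    pipeline, conventional EEG feature extraction (1/f-adjusted band power,
    mismatch waves, peak gamma, Morlet time-frequency power), and in-silico
    perturbation and sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
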