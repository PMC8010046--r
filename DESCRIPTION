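Package: clustlmm
Title: Cluster-Based Permutation Inference for Mixed-Model Neural Timecourses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate nested linear mixed-model likelihood-ratio
    timecourses with cluster-mass Monte-Carlo permutation inference for
    region-of-interest MEG/EEG source estimates, model-based estimated
    marginal means with multiplicity-adjusted contrasts, Morlet
    time-frequency decomposition with spectro-temporal cluster tests
    (induced versus evoked power), and information-theoretic syntactic
    metrics over transition probabilities. Includes a synthetic-data
    generator reproducing a 3x2x2 two-word plus 2x2 single-word factorial
    reading design (Latin-square blocks, participant random intercepts,
    Zipf-frequency and onset-time covariates, beta-band bursts) so every
    analysis stage is exercisable without any recording.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    digest,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
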