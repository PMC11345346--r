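Package: corrmem
Title: Memory and Belief Accuracy for Corrected Fake News: Simulation and
    Hierarchical MPT Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-phase fake-news-correction experiments
    in which participants rate headlines, detect corrections, and later
    retrieve real and fake news details. Provides a generative simulator of
    the full paradigm (two age groups, repetition-manipulated fake news,
    gated correction-remembering questions), equal-variance signal-detection
    estimation of correction detection and remembering (d-prime, criterion c),
    a hierarchical Bayesian dual-process multinomial processing tree model of
    recollection (Pr) and familiarity (Pf) with a latent-trait probit random
    effects structure fitted by Metropolis-within-Gibbs MCMC, posterior
    predictive fit checks for means and covariances, credible-difference
    summaries, and a descriptive pipeline of conditionalized retrieval
    proportions and belief-accuracy measures with cluster bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    coda
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
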