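Package: revlearn
Title: Computational Modelling of Serial Probabilistic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative simulation of a serial probabilistic reversal learning
    task, a family of seven reinforcement-learning models (single and dual
    learning rates, stimulus and side stickiness, experience-weighted
    attraction), hierarchical Bayesian estimation over a group-by-drug
    cell-means design with subject-level deviations, bridge-sampling
    estimation of marginal likelihoods and posterior model probabilities,
    HDI-based posterior contrasts, conventional reversal-learning behavioural
    measures with a classical statistical harness, and posterior-predictive
    simulation and parameter-recovery experiments on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
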