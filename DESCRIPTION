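Package: banditfit
Title: Simulation, Fitting and Recovery Audits for Reinforcement Learning
    Models of Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for computational modeling of trial-level choice
    behavior in multi-armed bandit and stimulus-action learning tasks.
    Implements generative behavioral models (biased random responding,
    noisy win-stay-lose-shift, Rescorla-Wagner learning with softmax
    choice, choice-kernel perseveration, and their combinations, plus
    side-bias and stimulus-blind/state-based variants), task simulators,
    maximum-likelihood fitting with guarded multistart optimization,
    BIC-based model comparison with confusion and inversion matrices,
    parameter- and model-recovery experiments, posterior predictive
    validation, and yoked latent-variable extraction (values, choice
    kernels, prediction errors).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
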