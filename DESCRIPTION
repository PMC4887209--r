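Package: bandit3arm
Title: Simulation and Credit-Assignment Analysis for Three-Armed Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing probabilistic three-option
    (three-armed bandit) reversal-learning experiments of the kind used in
    primate reward-guided decision-making studies. Provides generators for
    dynamically varying and fixed Bernoulli reward schedules with a
    mid-session reversal; Rescorla-Wagner value-learning agents with
    Boltzmann (softmax) action selection, including an eligibility-trace
    variant in which outcome credit for recently sampled options is
    attenuated; maximum-likelihood fitting of learning rates; a lagged
    choice-by-outcome logistic-regression kernel quantifying contingent
    credit assignment and spread-of-effect, combined across stimuli by an
    inverse-covariance-weighted mean; and descriptive analyses of switch/stay
    behaviour, choice-history conditions, choice-frequency effects,
    learning criteria and response latencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    sandwich,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
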