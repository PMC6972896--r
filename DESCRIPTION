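Package: complexitask
Title: Simulation and Analysis of a Complexity-Rewarded Sequential Choice Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a three-location sequential choice task in which
    reward delivery is deterministic and favors non-repetitive behavior:
    each choice is rewarded when the Lempel-Ziv complexity of the window of
    the nine past choices plus that choice is (weakly) maximal. Provides
    the reward rule and its exhaustive decision-tree enumeration,
    memory-augmented Rescorla-Wagner/softmax learning agents with U-turn
    costs and ambiguous state representations, sequence-variability
    statistics (normalized Lempel-Ziv complexity with constrained
    surrogates, recurrence-plot diagonal entropy, U-turn rates, surrogate
    randomness tests, pattern histograms), Markov-order and
    reward-conditioned transition analyses, fitness-based model fitting
    with approximate Bayesian model comparison, and generators for
    synthetic behavioral cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
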