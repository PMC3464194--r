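Package: rewardctl
Title: Reward- and Effort-Based Optimal Decision Making and Motor Control
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator for a unified model of decision making and motor
    control in which choices among actions, emergent movement durations and
    online feedback control all derive from a single infinite-horizon
    discounted utility: discounted reward minus discounted motor effort.
    Provides closed-form finite-horizon optimal control for linear plants
    (point mass, muscle-filtered point mass), a gradient-based solver for a
    two-joint planar arm, golden-section optimization of movement duration,
    receding-horizon closed-loop simulation with a delayed-observation
    Kalman estimator and signal-dependent motor noise, utility-based choice
    with indifference points and softmax choice probabilities, a
    synthetic-monkey cohort pipeline for spatial discounting, and
    config-driven experiment runners with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
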