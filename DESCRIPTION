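Package: nfadapt
Title: Bayesian Reinforcement-Learning Simulation of Neurofeedback
    Threshold Adaptation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates operant neurofeedback training for restorative
    brain-computer interfaces as a two-action Bayesian reinforcement-learning
    problem. A linear classifier with an adjustable decision threshold defines
    logistic reward-probability curves over a one-dimensional state continuum;
    the subject is a beta-Bernoulli learner that selects actions by comparing
    upper-tail beta confidences. Provides the deterministic expectation
    recursion and a stochastic Monte-Carlo sampler, action-entropy and
    instructional-efficiency metrics, fixed-threshold sweeps with
    entropy-minimizing and efficiency-maximizing threshold schedules, adaptive
    (open-loop) threshold replays with trace comparison, point-wise
    Kullback-Leibler reward-information analysis, and maximum-likelihood
    calibration of the logistic reward environment from binomial count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
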