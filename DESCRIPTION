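Package: loadctrl
Title: Personalized Training-Load Control with Deep Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and control toolkit for personalized athletic
    training-load prescription. Implements a fitness-fatigue-recovery
    athlete model (impulse-response performance dynamics, first-order
    fatigue ODE, multi-compartment exponential recovery), a daily-decision
    Markov decision process over a 16-week macrocycle with a four-component
    reward (performance gain, injury safety, adherence, recovery quality),
    and a deep Q-network agent with prioritized experience replay, soft
    target updates and an epsilon-greedy schedule. Ships baseline policies
    (linear periodization, physiological-threshold rules, regression-based
    prescription), reward-weight calibration by constrained grid search
    with cross-validation and sensitivity analysis, a seeded synthetic
    cohort generator with a sensor observation model and quality-control
    pipeline, phenotype clustering, fatigue-parameter estimation, and a
    paired policy-comparison harness with bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
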