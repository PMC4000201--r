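Package: trajcoh
Title: Trajectory Coherence Analysis for Non-Stationary Multi-Trial Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to discriminate deterministic non-autonomous drift from
    stochastic fluctuation in multi-trial, multivariate time series. Implements
    the trajectory incoherence (TI) statistic together with the machinery it
    rides on: a damped double-well (Duffing) benchmark generator with
    ground-truth basin labels and trial-wise parameter drift, polynomial state
    space expansions and the inhomogeneous polynomial kernel, a regularized
    (kernel) Fisher discriminant with trajectory-blocked cross-validation,
    fixed-reference trial-wise evaluation, surrogate null constructions
    (within-trajectory shuffling and randomized drift schedules), and
    comparison statistics (classification error, Priestley-Subba Rao
    stationarity test, Jensen-Shannon divergence, Wilks' lambda,
    Lilliefors-gated trial comparisons). A spike-train pathway (Gaussian
    spike-density estimation, binning, delay-coordinate embedding) supports
    neural ensemble recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
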