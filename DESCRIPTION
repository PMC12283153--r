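Package: megjoint
Title: Joint State-Space Estimation of MEG Sources and Directed Interactions
Version: 0.1.0
Authors@R:
    person("megjoint", "maintainers", email = "megjoint@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian estimation of neural source locations, source
    amplitudes and directed multivariate autoregressive (MVAR) interactions
    from multi-trial MEG-like sensor data. A Rao-Blackwellized conditional
    particle filter with ancestor sampling explores source-location
    trajectories while Kalman filtering/smoothing handles the conditionally
    linear amplitudes; model parameters are estimated by stochastic
    approximation EM. Includes an analytic spherical-conductor magnetometer
    forward model, LCMV/MCMV beamformer two-step baselines, generalized
    partial directed coherence with Fourier-transform surrogate significance,
    MVAR and evoked-response simulators with SNR calibration, and a metrics
    battery (source localization error, correct-hit rate, relative error,
    TPR/FPR, bootstrap summaries).
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
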