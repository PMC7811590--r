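Package: pulmouq
Title: Bayesian Uncertainty Quantification for 1D Pulmonary Haemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of pulse-wave propagation in a pulmonary
    arterial network by a two-step Lax-Wendroff scheme with three-element
    Windkessel outflow boundary conditions, and Bayesian calibration of the
    wall-stiffness and Windkessel scaling parameters from pressure time
    series. Supports independent-error and Gaussian-process model-mismatch
    likelihoods (neural-network covariance), adaptive Metropolis and
    Gibbs-within-Metropolis samplers including a hierarchical vessel-specific
    stiffness model, WAIC model selection, convergence diagnostics (Geweke,
    MPSRF), credible and prediction interval bands, a synthetic-data
    generator with signal-to-noise control and pressure-monotonicity
    rejection, and a Gaussian-process emulator of the log-posterior for
    accelerated sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
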