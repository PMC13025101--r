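Package: p3nmr
Title: Peak Probability Presentations for Multidimensional NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multidimensional protein NMR spectra into peak probability
    presentations (P3): per-point probabilities of a peak maximum, predicted by a
    compact gated convolutional network (MR-Ai) trained on synthetic spectra
    simulated from the damped complex-exponential signal model. Includes the
    synthetic-spectrum and noise simulators (Gaussian, Cauchy-Gaussian mixtures
    for non-uniformly sampled reconstructions, bimodal noise for skyline
    projections), Poisson-gap and uniform non-uniform sampling schedules with
    CS-IST compressed-sensing reconstruction, a probability-based peak picker
    (P5) with sub-pixel refinement, detection and probabilistic calibration
    statistics (F1 with vicinity matching, Brier and cross-entropy skill
    scores, reliability curves), and theoretical localization limits via
    Cramer-Rao lower bounds and Bayesian Monte Carlo posterior uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
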