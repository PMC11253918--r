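Package: fluorfit
Title: Error-Rate Estimation for Single-Molecule Protein Fluorosequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the per-cycle error rates that govern single-molecule
    protein fluorosequencing experiments (Edman cycle failure, dye loss,
    peptide detachment, missing fluorophores, and initial or cyclic
    N-terminal blocking) from radiometry reads of a known labeled peptide.
    Two independent fitters are provided: a factored hidden Markov model
    whose transition matrix is split into one sparse factor per error type,
    fit by a modified Baum-Welch algorithm that computes weighted maximum
    likelihood estimates of the underlying rates directly and corrects the
    missing-fluorophore rate for censoring of all-dud molecules; and a
    derivative-free fitter that reduces reads to integer dye tracks and
    minimizes the root-mean-square error between observed and simulated
    dye-track histograms with a coordinate trisection global search followed
    by coordinate-wise line minimization. A Monte Carlo simulator of the
    generative error model, intensity-distribution preprocessing, percentile
    bootstrap confidence intervals, and a command-line interface round out
    the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
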