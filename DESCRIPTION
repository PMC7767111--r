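Package: vcgmi
Title: Myocardial Infarction Classification from Single-Lead Derived
    Vectorcardiography
Version: 0.1.0
Authors@R:
    person("PKG", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing three-lead Frank vectorcardiograms
    (VCG) from a single-lead ECG with a patient-specific sliding-window
    recurrent network, representing each heartbeat by least-squares
    B-spline coefficients, and classifying beats into eleven myocardial
    infarction localization classes plus healthy controls with a
    SMOTE-balanced multilayer perceptron.  Includes a seeded synthetic
    multi-lead ECG generator (shared dipole source, Gaussian
    characteristic waves, class-conditional morphology), WFDB and
    delimited-text signal I/O, zero-phase band-pass preprocessing,
    Pan-Tompkins R-peak detection, beat period normalization, and a
    full multiclass evaluation suite (confusion matrices, per-class and
    overall accuracy/sensitivity/specificity).
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
    splines,
    optparse
Config/testthat/edition: 3
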