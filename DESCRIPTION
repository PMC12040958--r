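Package: ecgvae
Title: Conditional Generation of 12-Lead ECGs and Latent-Space Cardiovascular Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for personalized 12-lead electrocardiogram modelling. Computes
    subject-specific heart position, orientation (heart-local coordinate frame and
    Euler angles) and electrode-coordinate transforms from cardiac MRI plane
    metadata; preprocesses raw 12-lead records into quality-controlled 12x400
    median beats (FIR band-pass, R-peak detection, median-beat extraction, cohort
    filtering, stratified splits); trains a conditional variational autoencoder on
    median beats with anatomical and demographic conditioning; attaches a Cox
    partial-likelihood risk head to the latent space for cardiovascular risk
    prediction (concordance index, Kaplan-Meier stratification); and provides a
    dipole volume-conductor simulator generating pose- and electrode-dependent
    synthetic beats with proportional-hazards survival outcomes for desk-scale
    experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    survival,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
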