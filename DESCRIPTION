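Package: agfinger
Title: Silver-Adduct LDI-MS Metabolic Fingerprinting for Newborn PKU Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for label-free dried-blood-spot metabolic fingerprinting by
    silver-nanoparticle-assisted laser desorption/ionization mass spectrometry
    (LDI-MS), aimed at phenylketonuria (PKU) screening and PAH-versus-BH4 subtype
    identification. Implements spectral preprocessing (baseline correction, peak
    detection, alignment, top-k fingerprint selection, normalization and
    standardization), nested cross-validated elastic-net logistic classification
    with selection-frequency tracking and comparator models (ridge, k-nearest
    neighbours, naive Bayes), ROC/AUC machinery with DeLong confidence intervals
    and tests, three-criterion biomarker selection exploiting 107Ag/109Ag isotope
    adduct doublets, a two-step screening plus subtype decision procedure, and a
    seeded synthetic-cohort generator with known ground truth for validation and
    power analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
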