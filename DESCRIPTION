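Package: fbdkit
Title: Formulation-by-Design Toolkit for HPLC Method Optimization,
    Validation, Release Kinetics and Noncompartmental Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the quality-by-design development of
    chromatographic assays and nanoparticle formulations: screening
    (Taguchi orthogonal array) and face-centred central composite
    designs with coded/actual level mapping, second-order
    response-surface model fitting with lack-of-fit ANOVA and
    Derringer-Suich desirability-based multi-response optimization,
    ICH-style analytical method validation statistics (calibration
    linearity, LOD/LOQ, precision, accuracy, system suitability),
    encapsulation efficiency and sampling-corrected drug-release
    kinetics (zero-order, first-order, Higuchi), and non-compartmental
    pharmacokinetic analysis (Cmax, tmax, lambda-z, AUC, AUMC, MRT)
    with Welch group comparison. Includes seeded simulators for every
    input class so each stage can be tested against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
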