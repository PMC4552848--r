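Package: thoraciq
Title: Quantitative CT and Respiratory-Mechanics Pipeline for Early-Onset
    Thoracic Deformity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement chain linking three-dimensional spine deformity to
    lung growth and respiratory function in small-animal breath-hold CT
    studies.  Provides synthetic thorax phantoms with known ground truth,
    centerline-based Cobb and composite deformity angles, Hounsfield-unit
    lung densitometry (mass, aerated volume, fractional tissue volume,
    FRC/TLC/IC), multi-resolution deformable registration with
    Jacobian-based specific-volume mapping and regional analysis,
    recursive-least-squares estimation of single-compartment respiratory
    mechanics, forced vital capacity with repeatability gating, and
    cohort-level percent-of-normal summaries and deformity-outcome
    regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
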