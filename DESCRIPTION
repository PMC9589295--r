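Package: sctqa
Title: Voxel-Wise Population-Based Quality Assurance for Synthetic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-based, voxel-wise quality assurance of
    synthetic CT (sCT) generation in MRI-only radiotherapy planning of the
    male pelvis. Provides per-patient image and dose error maps (AE, E, APE
    and their regional means), an organ-driven inter-patient registration
    pipeline (structural descriptions from distance and Laplace fields,
    template selection, rigid and free-form prealignment, staged
    multi-resolution diffeomorphic Demons, Dice-gated quality control and
    spongy/cortical bone refinement) bringing a cohort to a common
    coordinate system, voxel-wise population statistics (vMAE, vME, vMAPE,
    RSD of the absolute error) with a studentized sign-flip paired
    permutation test, and dose-comparison metrics (mean-absolute-dose-error
    volume histograms, DVH criteria, 3D gamma analysis). A fully synthetic
    pelvic phantom cohort generator (paired CT, MRI-like image, organ
    masks, bulk-density and learned-like sCT surrogates, analytic ray-cast
    dose engine) makes the whole workflow runnable and testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
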