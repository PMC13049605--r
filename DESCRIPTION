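Package: protonrem
Title: Scenario-Based Robustness Evaluation for Pencil-Beam-Scanning Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying setup-uncertainty reduction in
    intensity-modulated proton therapy of mediastinal lymphoma. Provides a
    synthetic 10-phase breathing thorax phantom with ground-truth deformation
    fields, an analytic pencil-beam-scanning dose engine with setup and range
    perturbations, minimax robust spot-weight optimization and dose-mimicking
    re-optimization, 3D (voxel-wise minimum over 28 scenarios) and 4D
    (per-fraction interplay simulation with dose accumulation) robustness
    evaluation, DVH and organ-of-interest dose metrics, a Darby-form acute
    coronary event NTCP model with a model-based selection gate, and paired
    nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    RNifti,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
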