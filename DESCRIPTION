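Package: sbrtDoseConv
Title: Patient-Feature Modeling of Pencil-Beam to Monte Carlo Target Dose
    Conversion in Lung SBRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify and model the loss of target coverage when
    lung stereotactic body radiotherapy (SBRT) plans computed with a
    pencil-beam (Type-A) dose algorithm are recalculated with Monte Carlo.
    Provides anisotropic distance-transform geometry for structure
    expansion, shells and distance indices; Hounsfield-unit density
    feature extraction; DVH dose-at-volume and percent-deficiency
    metrics; single and multiple linear regression with F-test
    significance, published two-feature conversion models, and a
    single-hidden-layer neural-network regressor with weight-decay grid
    search and leave-one-out cross-validation; plus a synthetic thoracic
    phantom and cohort generator so the whole pipeline is testable
    end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    nnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
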