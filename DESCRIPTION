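Package: GKRadiomics
Title: Radiomics Pipeline for Gamma Knife Radiosurgery Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end MRI radiomics pipeline for predicting local tumor
    control and overall survival of brain metastases treated with Gamma Knife
    radiosurgery. Provides synthetic multi-contrast phantom cohorts with
    planted texture and clinical effects, image preprocessing (isotropic
    resampling, rigid mutual-information registration, Z-score
    normalization), a 1763-entry radiomic feature extractor (histogram,
    GLCM, GLRLM, LBP and geometry families on the original images and eight
    undecimated 3D coif1 wavelet subbands), outcome labeling, two-step
    feature selection (Welch t-test ranking plus sequential forward
    selection), NearMiss-2 class balancing, RBF support vector machine
    training with Bayesian hyperparameter optimization, and paired bootstrap
    model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    e1071,
    lhs
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
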