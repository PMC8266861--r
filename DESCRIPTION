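Package: earlypcr
Title: Early Prediction of Pathological Complete Response from DCE-MRI via
    Transfer-Learning Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for predicting pathological complete response
    (pCR) to neoadjuvant chemotherapy from dynamic contrast-enhanced breast
    MRI at pre-treatment and early-treatment timepoints. Tumors are segmented
    from peak-enhancement and signal-enhancement-ratio maps, a square region
    of interest sized by the clinical largest diameter is resized to 227x227
    and passed through a fixed convolutional feature extractor honouring the
    AlexNet pool2 contract (13x13x256, 43264 features per timepoint). Stable
    discriminative features are selected by an iterated, resampled
    Wilcoxon-Mann-Whitney filter (union within iteration, intersection across
    iterations, intersection across leave-one-out patients), yielding an
    optimal subset of features used by a support vector machine evaluated by
    leave-one-patient-out cross-validation and on an independent test set,
    with ROC/AUC, Youden-index thresholding and clinical-covariate
    integration. A seeded synthetic-data module generates DCE phantoms,
    planted-feature cohorts and clinical tables so the whole pipeline is
    exercisable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    grDevices,
    igraph,
    jsonlite,
    RNifti,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
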