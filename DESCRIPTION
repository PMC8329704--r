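Package: nfblearn
Title: Multimodal Baseline Predictors of SMR Neurofeedback Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying within-session learning during sensorimotor
    rhythm (SMR, 12-15 Hz) up-regulation neurofeedback. Implements the online
    feedback computation (sliding-window FFT band power, adaptive median
    thresholding, reward scoring) and the learning index (mean per-session
    regression slope of run-median SMR power); extraction of baseline features
    from resting EEG (Welch relative band power over scalp regions), resting
    fMRI (ALFF, fALFF, regional homogeneity, ROI-sphere functional
    connectivity) and voxel morphometry maps; correlation-based predictor
    screening with permutation and false-discovery-rate inference; and
    leave-one-out prediction of the learning index from single-modality and
    multimodal feature sets. A synthetic multimodal cohort generator with
    planted, parameterised feature-learning relations makes every stage
    testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    RNifti,
    e1071,
    randomForest,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
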