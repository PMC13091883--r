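Package: recallFC
Title: Scene-Level Memory Recall Classification from Narrative fMRI
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking narrative event structure to brain network
    dynamics and memory. Merges multiple annotators' recall-question-anchored
    scene segmentations of an audio narrative into consensus scene windows,
    maps scene times onto fMRI acquisition frames, computes per-scene
    Pearson functional-connectivity features from ROI time series, separates
    the stacked connectivity matrices into a shared low-rank component and
    subject-specific sparse deviations by robust principal component
    analysis, and classifies scene-level memory recall with leave-one-out
    cross-validation, label-shuffling null distributions, paired accuracy
    comparisons and calibration curves. A seeded synthetic-study generator
    with planted shared/idiosyncratic connectivity structure makes every
    stage testable without access to fMRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    glmnet,
    ranger,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
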