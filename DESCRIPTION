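Package: dyskscore
Title: Automated Video-Based Scoring of Dystonia from Markerless Keypoint Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated assessment of dystonia severity in dyskinetic
    cerebral palsy from 2D keypoint time series extracted by markerless motion
    trackers. Reads per-video keypoint tables (DeepLabCut-style CSV), applies
    likelihood masking, gap interpolation and cyclic length extrapolation,
    computes three geometric posture features (distance-to-middle-point,
    distance-to-bodyline, joint angle) reduced to windowed medians, and trains
    subject-grouped cross-validated random-forest regressors against normalized
    Dyskinesia Impairment Scale amplitude scores. Includes tracking-accuracy and
    inter-rater agreement metrics and a synthetic stick-figure cohort generator
    with known severity ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
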