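Package: palscale
Title: Psychophysical Scaling of Perceived Spectacle-Lens Distortions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring and modelling the perceived severity of
    progressive-addition-lens (PAL) geometric distortions from
    comparison-based (triplet) similarity judgments. Provides the full
    analysis chain: triplet experimental design with catch trials, soft
    ordinal embedding of responses into a perceptual scale,
    cross-validated dimensionality selection, bootstrap robustness,
    generalized Procrustes alignment and normalization across observers,
    predictive scale models (linear, exponential, random forest) with
    leave-one-subject-out evaluation, and head/gaze behavioral analysis
    (Tait-Bryan angles, angular velocities, gaze-density area, rank
    tests, full-interaction linear models). A synthetic-observer
    simulator generates triplet choices, head-orientation traces and
    gaze samples so the pipeline can be exercised and validated without
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
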