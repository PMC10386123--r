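Package: cogload
Title: Cognitive-Load Classification from Wearable Physiological Signals
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline linking wrist-worn physiological
    recordings (photoplethysmography, skin conductance, accelerometry,
    skin temperature at 51.2 Hz) to binary cognitive-load classification
    and food-choice behaviour. Provides a synthetic session generator,
    accelerometer-based clock synchronisation, Butterworth filtering,
    photoplethysmography beat detection with sequential inter-beat-interval
    gating, sparse convex decomposition of electrodermal activity into
    tonic, phasic and sudomotor-driver components, artefact-gated sliding
    windows with a 125-feature catalogue, hybrid feature selection
    (ANOVA filter plus recursive feature elimination with
    cross-validation), nested leave-one-subject-out grid-search
    classification, questionnaire and food-consumption statistics, and
    per-subject aggregation with hierarchical clustering of food items.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite,
    quadprog,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
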