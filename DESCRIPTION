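Package: cropvision
Title: Selective Prediction and Evaluation for Crop-Photo Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing and evaluation pipeline for crop-type image
    classifiers trained on geo-tagged field photos. Implements
    information-theoretic uncertainty scoring of softmax outputs
    (self-information, Shannon entropy, expected information divergence and
    the equivalent reference probability), automated threshold search and
    quadrant filtering for selective prediction, confusion-matrix metrics
    (overall, producer and user accuracy, macro-F1, class grouping,
    unfavorable-condition reports), crop-calendar harmonization with
    half-month maturity windowing, stratified cohort construction, a
    synthetic-data generator emulating classifier outputs over European
    crop classes, and a classifier-agnostic two-round random
    hyperparameter-search harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
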