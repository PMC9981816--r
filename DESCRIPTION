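Package: cogem
Title: Cognitive Encoding Models for Task fMRI Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits region-wise cognitive encoding models (CEMs) that map
    ontological task annotations to parcellated cortical activation with
    ridge regression and nested cross-validation, and evaluates their
    generalization to held-out tasks with a leave-two-out two-way
    classification scheme. Includes a task-shuffled permutation null model,
    noise-ceiling estimation from between-session reliability, clustering
    of ontological features from classifier confusions, between-subject
    model transfer, and resting-state-network feature importances, together
    with a synthetic-data generator with known ground truth for testing
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
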