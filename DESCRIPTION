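Package: gadnn
Title: Genetic-Algorithm Feature Selection with Deep Neural Networks for
    Sinus Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sex classification, four-group age classification and continuous
    age regression from twelve CBCT-derived frontal and maxillary sinus
    measurements. Implements the GADNN method: a binary-chromosome genetic
    algorithm that searches feature subsets using the held-out accuracy of a
    fixed nine-layer dense neural network as its fitness, together with SMOTE
    class balancing, min-max normalisation, one-hot encoding, stratified
    splitting, confusion-matrix and regression metrics, classical baseline
    models, and a seeded synthetic-cohort generator for testing every stage
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
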