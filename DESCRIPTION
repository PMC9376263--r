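Package: fundusDR
Title: Diabetic Retinopathy Grading with HOG-PCA Features and a Gray
    Wolf Optimized Extreme Learning Machine
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for grading diabetic retinopathy severity from retinal
    fundus photographs. Implements the full pipeline: image pre-processing
    (grayscale conversion, contrast stretching, bicubic resizing to
    255x255), Histogram of Oriented Gradients (HOG) descriptors, principal
    component reduction of the descriptor matrix, and an Extreme Learning
    Machine classifier whose input weights and hidden biases are tuned by
    Gray Wolf Optimization with classification accuracy as the fitness.
    Includes a synthetic fundus-image and feature-table generator for
    fully reproducible experiments, a stratified train/test protocol with
    binary and five-class evaluation, and one-vs-rest micro-averaged
    confusion metrics (accuracy, precision, recall, specificity,
    F-measure, G-mean, Matthews correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
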