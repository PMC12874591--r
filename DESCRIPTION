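Package: odorgng
Title: Analysis of Odor-Guided Go/No-Go Task Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for event-aligned spike-train analysis in an
    odor-guided go/no-go task: sliding-bin auROC selectivity with permutation
    nulls, response-shape measures (center of mass, onset, duration), a
    lagged-binary-predictor encoding model with relative contributions,
    population trajectory analysis by PCA with baseline-thresholded
    condition distances, pseudo-population linear-SVM decoding over time and
    population size, and trial-order stability tests. A synthetic session
    generator emulates the task timeline and the principal neuron response
    archetypes so every stage is exercisable, with ground truth, without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
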