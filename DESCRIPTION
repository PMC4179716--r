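Package: gbnet
Title: Gaussian Bayesian Networks for Regional Gray-Matter Structural Associations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Learns group-level linear Gaussian Bayesian networks over regional
    gray-matter volumes by BIC-scored greedy hill-climbing, tests between-group
    differences in connection weight coefficients with a relearn-per-permutation
    test, and classifies subjects by comparing joint log-densities under the two
    group models. Includes ROI mean-volume extraction from labelled NIfTI masks,
    a synthetic two-group cohort generator with built-in auditory, visual and
    motor network templates, an exhaustive DAG enumerator used as a small-graph
    oracle, and CPDAG (Markov equivalence class) utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
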