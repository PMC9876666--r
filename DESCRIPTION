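Package: mvdf
Title: Multiview Deep Forest for Clinical Survival-Class Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a multiview deep forest (MVDF) classifier for
    multiclass prediction on clinical tabular data with a view structure,
    such as discretized overall-survival outcomes. The pipeline extracts
    class-vector features from pairs of completely-random and Gini-split
    forests trained on every non-empty subset of views, selects important
    indicators by Gini importance and expert knowledge, compresses the
    remaining indicators with a variational information-bottleneck encoder,
    builds boosted two-tree correction features with multiclass gradient
    leaf values, and classifies with a cascade of forests whose trees are
    pruned by a score-based keep probability. A synthetic cohort generator
    with multiview signal, cross-view redundancy and missingness makes the
    whole system testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
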