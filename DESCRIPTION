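Package: codephen
Title: Data-Driven Phenotyping of Rheumatoid Arthritis from Coded
    Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for deriving and validating electronic-health-record
    phenotyping algorithms from linked primary- and secondary-care coded
    data. Implements relative-frequency screening of clinical codes against
    a gold-standard diagnosis, seed-based aggregation of related codes by
    hierarchy prefix and active ingredient, a subsampled ensemble of
    Gini-impurity classification trees for importance ranking with
    out-of-bag error estimation, single-tree gain-ratio rule induction with
    pessimistic pruning, a configurable rule engine for a published
    eight-predictor rheumatoid-arthritis classifier, and best/worst-case
    scenario validation of diagnostic accuracy under incomplete record
    linkage. A synthetic linked-EHR simulator with planted case/control
    signal makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    igraph,
    rpart,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
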