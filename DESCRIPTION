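Package: searchprint
Title: Digital Phenotyping from Personal Search-Activity Archives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning time-stamped personal search logs into
    clinical-state classifiers. Parses Google Takeout "My Activity" search
    archives and clinical hospitalization timelines, segments each archive
    into labeled 4-week observation windows around psychiatric
    hospitalizations, extracts a 123-dimension feature vector combining
    circadian query histograms with lexicon-based word-category proportions
    (LIWC-style .dic dictionaries), evaluates random forest, RBF support
    vector machine and gradient boosting classifiers under stratified
    5-fold cross-validation, and ranks features by AUC-based permutation
    importance. Includes a seeded synthetic-cohort generator so the whole
    pipeline is testable without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    dplyr,
    ranger,
    e1071,
    xgboost,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
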