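Package: p300elm
Title: P300 Classification with F-Score Feature Ranking and Extreme
    Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying P300 event-related potentials from
    guilty-knowledge-test probe stimuli. Simulates averaged ERP epochs,
    performs baseline correction and trial averaging, extracts 31
    time-domain, Burg-spectral and wavelet-approximation features,
    ranks features by F-score, trains extreme learning machine (ELM)
    classifiers with minimal-norm least-squares output weights, and
    jointly optimizes the feature-subset size and the hidden-node count
    by grid search under subject-wise cross-validation with an inner
    10-fold loop. Includes a PCA comparator transform, balanced-accuracy
    evaluation and paired t-tests between per-fold accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
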