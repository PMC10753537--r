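Package: mirmod
Title: MiRNA Module Biomarker Discovery from Multi-View Networks and
    Q-Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate miRNA module biomarkers from expression
    data and curated miRNA-disease relations. A cooperative-regulation
    network is built from rank tests on pairwise relative-expression
    features, a functional-similarity network from a weighted
    best-matching average over embedded disease terms, and the two views
    are fused, sparsified by a maximum-spanning-tree plus
    k-nearest-neighbour backbone with power-law-guided choice of k, and
    searched for discriminative modules by tabular Q-learning. Per-module
    linear support-vector classifiers are combined by weighted voting and
    evaluated with repeated stratified cross-validation. A synthetic-data
    generator with planted differential modules makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
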