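Package: opitrade
Title: Text Mining of Opioid Trading on Anonymous Marketplaces and Forums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for profiling opioid trading
    activity on anonymous (darknet) marketplaces and forums: dual-corpus
    skip-gram embeddings that surface drug jargon by comparing a word's
    underground-context vector with known opioid keywords' benign-context
    vectors; an imbalance-weighted, L1-regularised transfer-learning classifier
    for promotion and review forum posts; rule-based extraction of structured
    trading properties (per-gram prices with median-based outlier filtering,
    origins and shipping destinations, escrow, sold counts); chi-square
    feature-scored review sentiment; and supply-chain analytics (listing churn,
    cross-market duplicate listings, supplier Jaccard overlap, supplier
    migration after market closures). A synthetic-data generator with full
    ground truth stands in for scraped darknet corpora so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
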