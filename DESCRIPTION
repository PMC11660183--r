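Package: foodenv
Title: Food Environment Classification from Storefront Names
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building categorized food-environment datasets from
    administrative storefront directories. Converts source taxonomy tags to
    ten non-exclusive food retail classes, builds leakage-controlled
    train/validation/test datasets with modal deduplication and chain
    memorization, trains a multi-label store-name classifier (one-vs-rest
    regularized log-linear over word and character n-grams), evaluates with
    per-class precision/recall/F1 plus micro/macro aggregates and published
    sensitivity cutoff bands, computes per-hexbin mean annual churn of store
    types, and audits externally tagged datasets by cross-tabulating
    classifier labels against tag fields. Includes a synthetic storefront
    directory generator so the whole pipeline is testable without access to
    licensed directory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    stringi,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
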