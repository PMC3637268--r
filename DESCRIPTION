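Package: acode
Title: Co-Expression Network Communities and Single-Gene Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks from expression
    matrices (Spearman correlation with a signed threshold), detects
    strongly co-expressed communities with A-CODE, an edge-seeded greedy
    search scored by co-expression compactness (mean over standard
    deviation of edge weights) with permutation-based q-values, and fits
    single-gene ridge-penalised logistic classifiers evaluated by
    leave-one-out cross-validated ROC/AUC with permutation significance.
    Includes per-gene differential expression (pooled-variance t-test with
    Benjamini-Hochberg adjustment), efficiency-corrected qPCR relative
    quantification, a synthetic-data generator with planted co-expression
    modules and case/control marker effects, and a reproducible pipeline
    driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
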