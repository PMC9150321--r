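Package: sctumor
Title: Tumor Cell Classification for Single-Cell RNA-Seq by Gene-Set
    Scoring, Label Propagation, and Copy-Number Proofreading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step machine-learning workflow that separates tumor cells
    from normal cells in annotated single-cell RNA-seq data. Tumor-enriched
    and tumor-depleted gene signatures are derived by per-dataset
    differential expression followed by cross-dataset consolidation; cells
    are scored with a rank-based recovery-curve (AUCell-style) statistic; a
    logistic classifier on the two scores yields class probabilities that
    are refined by iterative label propagation over a signature-gene
    cell-cell graph with an exponentially decaying stringency threshold; an
    optional proofreading step infers smoothed copy-number profiles from
    expression and flips highly probable discordant labels. Includes a
    negative-binomial cohort simulator with planted markers, batch effects,
    and copy-number segments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    methods,
    randomForest,
    rhdf5,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
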