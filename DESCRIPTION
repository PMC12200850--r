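Package: reosig
Title: Rank-Based Qualitative Gene-Pair Signatures from Relative
    Expression Orderings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and single-sample application of qualitative
    transcriptomic signatures built from within-sample relative expression
    orderings (REO) of gene pairs. Mines gene pairs whose ordering is
    highly stable within each phenotype class, intersects the two classes
    to find reversed pairs, restricts candidates to a user-supplied gene
    set, and classifies individual samples by a winner-takes-all vote that
    is invariant to any monotone per-sample transformation (and therefore
    to batch and normalization effects). Includes confusion-matrix and
    ROC/AUC evaluation, single-sample gene-set enrichment (ssGSEA)
    immune-infiltration scoring, Wilcoxon rank-sum differential expression
    with Benjamini-Hochberg control and cross-cohort consistency,
    Spearman co-expression networks around seed genes, hypergeometric
    over-representation, and a synthetic two-class cohort generator with
    planted reversed pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
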