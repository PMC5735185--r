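Package: metasig
Title: Cross-Study Gene-Signature Biomarker Scoring and Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives activated/repressed target-gene signatures from
    over-expression experiments (single-threshold and dual-construct
    dominant-negative selection rules), computes single-sample signature
    scores (mean of up-targets, or a within-sample t-statistic contrasting
    up- and down-targets) on case/control expression cohorts, and assesses
    discriminatory power by per-study Wilcoxon rank-sum tests,
    DerSimonian-Laird random-effects pooling with Fisher's combined
    probability test, ROC/AUC comparison via DeLong's test, a matched-size
    random-gene-set resampling null, and Fisher's-exact gene-set
    over-representation with robust inverse-enrichment pairing. Includes
    seeded simulators for multi-study case/control cohorts and paired
    over-expression/dominant-negative experiments with planted targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    pROC,
    DESeq2
Config/testthat/edition: 3
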