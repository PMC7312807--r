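Package: injurymod
Title: Injury-Module Activation Scoring for Toxicogenomic Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Gene-set activation analysis for toxicogenomic expression
    studies. Computes per-gene log fold changes and t-tests from paired
    treatment/control cohorts, calls differentially expressed genes with
    FDR and effect-size thresholds, and scores organ injury modules with
    the aggregate absolute fold-change (AAFC) statistic: a permutation
    null over random gene sets yields a z-score and empirical p-value per
    module, and Fisher's combined probability summarises the reliability
    of the member genes' fold changes. A cross-system layer compares
    conditions across species and culture systems via ortholog-mapped DEG
    overlap with chance expectation, Pearson correlation of module
    activation vectors, condition-level PCA, and hypergeometric gene-set
    enrichment. A synthetic-data generator with known ground truth makes
    every stage testable without external data, and a pipeline runner
    orchestrates simulate/fc/deg/score/compare stages reproducibly.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
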