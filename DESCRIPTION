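Package: methorigin
Title: Tissue-of-Origin Classification from Read-Level DNA Methylation Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts the primary site of a tumor sample from bisulfite
    methylation haplotypes over CpG-island regions. Reads mHap-style
    haplotype files, computes four read-level methylation statistics
    (beta value, proportion of discordant reads, cell
    heterogeneity-adjusted clonal methylation, and methylated haplotype
    load), selects cancer-type-specific marker islands with a
    two-condition Wilcoxon rank-sum / false discovery rate procedure,
    trains and calibrates a grid of multiclass classifiers with
    stratified splitting and synthetic minority oversampling, and
    evaluates ranked top-k predictions. Includes a synthetic methylome
    simulator with tumor-purity mixing for end-to-end validation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    ranger,
    glmnet,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
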