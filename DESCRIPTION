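Package: epigx
Title: Integrated Genetic-Epigenetic Association Scans for a Target CpG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrated genetic-epigenetic analysis of a single
    focal methylation probe against a quantitative glycemic exposure (HbA1c).
    Provides a synthetic cohort generator with planted effects and known ground
    truth; genotype quality control (minor-allele-frequency filtering and
    windowed linkage-disequilibrium pruning); glycemic-status binning and
    exclusion rules; stochastic-epimutation (3xIQR fence) outlier detection,
    burden summaries, enrichment testing and probe filtering; vectorized
    genome-wide least-squares scans (EWAS, polymorphic-probe, meQTL with
    cis/long-range-cis/trans partitioning, SNP-by-exposure and
    CpG-by-SNP interaction scans) with Benjamini-Hochberg, Bonferroni and Holm
    multiple-testing control; step-wise construction of integrated variance
    models with nested-model F-tests and genotype-stratified methylation
    comparisons; and imbalance-aware disease-status classification via logistic
    baselines and balanced random forests with repeated stratified
    cross-validation, implicit feature selection and Gini-importance pruning.
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
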