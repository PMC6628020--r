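Package: dxmeta
Title: Diagnostic Test Accuracy Meta-Analysis of Expression Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logistic-regression-based diagnostic meta-analysis for gene
    expression biomarkers. Per-study univariate logistic classification of
    case/control expression turns each cohort into a 2x2 diagnostic table;
    the tables are pooled into sensitivity, specificity, likelihood ratios
    and the diagnostic odds ratio with DerSimonian-Laird random effects and
    Cochran Q / I-squared heterogeneity, and summarised by a
    Moses-Littenberg summary ROC curve with AUC and the Q* point. Includes
    a multi-study synthetic cohort generator, quantile-normalisation
    preprocessing for log2 microarray intensities, per-group expression
    summaries and Pearson similar-gene ranking, with a worked reproduction
    of a published chromogranin-A (CHGA) colon-cancer screening analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
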