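#!/usr/bin/env Rscript

# Step 3 — run the end-to-end pipeline (normalise -> per-study logistic
# classification -> 2x2 tables -> pooling -> SROC) on the synthetic set,
# scoring the marker against a panel of noise genes, and export the
# per-group expression summaries behind the verification boxplots.
#
# Finds: CHGA tops the comparison by DOR and AUC with an operating point
# near sens = spec = 0.89, while noise genes sit at chance; its case median
# lies below the control median in every study.

suppressPackageStartupMessages(library(dxmeta))

dir.create("results", showWarnings = FALSE)
set <- generate_chga_cohorts(seed = 20260922L)
genes <- c("CHGA", sprintf("NOISE%03d", 1:10))

report <- suppressMessages(run_pipeline(set, genes))
report[-1] <- lapply(report[-1], function(x) round(x, 4))
print(report)
write.csv(report, "results/biomarker_report.csv", row.names = FALSE)

gs <- group_summaries(set, "CHGA")
gs[3:7] <- lapply(gs[3:7], function(x) round(x, 4))
print(gs)
write.csv(gs, "results/chga_group_summaries.csv", row.names = FALSE)

cat("Wrote results/biomarker_report.csv and results/chga_group_summaries.csv\n")
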