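#!/usr/bin/env Rscript
# Stage 3: inter-observer reproducibility filter.
#
# Two-way single-measure absolute-agreement ICC per feature across the two
# observers' contours; features with ICC >= 0.8 are kept for all further
# analysis. Output: results/icc_report.csv + the kept feature table.

suppressPackageStartupMessages(library(crtradiomics))

t1 <- read.csv("results/features_obs1.csv", check.names = FALSE)
t2 <- read.csv("results/features_obs2.csv", check.names = FALSE)
res <- filter_reproducible(t1, t2, threshold = 0.8)
write.csv(res$results, "results/icc_report.csv", row.names = FALSE)
write.csv(t1[, c("case_id", res$kept)], "results/features_kept.csv",
          row.names = FALSE)

message(sprintf("%d / %d features reproducible (ICC >= %.1f)",
                length(res$kept), nrow(res$results), res$threshold))
message("non-reproducible features by family:")
print(res$by_family)
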