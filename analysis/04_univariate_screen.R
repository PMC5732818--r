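#!/usr/bin/env Rscript
# Stage 4: univariate screening of the reproducible features.
#
# Kruskal-Wallis contrasts (responders vs nonresponders, SD vs PR, SD vs CR),
# ROC analysis with Youden cut-offs for the significant features
# (nonresponder as positive class), and DeLong pairwise AUC comparison of
# the top features. Raw p-values throughout; no multiplicity correction.
# Outputs: results/screen_contrasts.csv, results/screen_roc.csv,
# results/delong_pairs.csv.

suppressPackageStartupMessages(library(crtradiomics))

kept <- read.csv("results/features_kept.csv", check.names = FALSE)
cohort <- read.csv("results/cohort/cohort.csv")
stopifnot(identical(kept$case_id, cohort$case_id))

scr <- univariate_screen(kept, cohort$label)
write.csv(scr$contrasts, "results/screen_contrasts.csv", row.names = FALSE)
roc_tab <- do.call(rbind, lapply(scr$roc, function(r)
  data.frame(feature = r$feature_name, p_value = r$p_value, se = r$se,
             ci_low = r$ci95[1], ci_high = r$ci95[2], auc = r$auc,
             cutoff = paste0(r$side, signif(r$cutoff, 6)),
             sensitivity = r$sensitivity, specificity = r$specificity)))
write.csv(roc_tab, "results/screen_roc.csv", row.names = FALSE)
message(sprintf("%d features significant for responders vs nonresponders",
                length(scr$significant)))
print(head(roc_tab[order(-roc_tab$auc), ], 5), row.names = FALSE)

# pairwise DeLong comparison of the five best-AUC features
top <- head(roc_tab$feature[order(-roc_tab$auc)], 5)
positive <- !cohort$responder
pairs <- t(combn(top, 2))
dl <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  d <- delong_test(kept[[pairs[i, 1]]], kept[[pairs[i, 2]]], positive)
  data.frame(feature_a = pairs[i, 1], feature_b = pairs[i, 2],
             auc_a = d$auc_a, auc_b = d$auc_b, z = d$z, p_value = d$p_value)
}))
write.csv(dl, "results/delong_pairs.csv", row.names = FALSE)
message(sprintf("DeLong pairwise comparisons of the top %d features written",
                length(top)))
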