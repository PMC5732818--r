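#!/usr/bin/env Rscript
# Stage 5: classifier construction and validation.
#
# On the training split only: univariate pre-ranking cap, wrapper-based
# backward feature elimination per algorithm (SVM and single-hidden-layer
# neural network), 10-fold cross-validation metrics, McNemar comparison of
# the out-of-fold predictions, then hold-out evaluation on the untouched
# test split. Outputs: results/cv_metrics.csv, results/holdout_metrics.csv,
# results/selected_features.csv.

suppressPackageStartupMessages(library(crtradiomics))

seed <- 1L
kept <- read.csv("results/features_kept.csv", check.names = FALSE)
cohort <- read.csv("results/cohort/cohort.csv")
train <- cohort$split == "train"
y <- cohort$responder
feat_names <- setdiff(names(kept), "case_id")

# cap wrapper input at the 15 best training-split Kruskal-Wallis features
p_train <- vapply(feat_names, function(f)
  kruskal_wallis(kept[[f]][train], ifelse(y[train], "R", "NR"))$p_value,
  numeric(1))
top <- feat_names[order(p_train)][1:min(15, length(feat_names))]
message(sprintf("wrapper selection over the top %d training-ranked features", length(top)))

models <- list(); rows <- list(); hold_rows <- list(); sel_rows <- list()
for (algo in c("svm", "ann")) {
  cfg <- model_config(algo, n_folds = 10L, seed = seed + 41L)
  sel <- wrapper_select(kept[train, c("case_id", top)], y[train], cfg)
  cv <- cross_validate(kept[train, c("case_id", sel$selected)], y[train], cfg)
  fit <- train_classifier(kept[train, c("case_id", sel$selected)], y[train], cfg)
  hold <- evaluate_holdout(fit, kept[!train, c("case_id", sel$selected)], y[!train])
  models[[algo]] <- list(cv = cv, hold = hold)
  grab <- function(m) unlist(m[c("tp_rate", "fp_rate", "precision", "accuracy",
                                 "f_measure", "mcc", "auc")])
  rows[[algo]] <- data.frame(algorithm = algo, t(grab(cv$metrics)))
  hold_rows[[algo]] <- data.frame(algorithm = algo, t(grab(hold$metrics)))
  sel_rows[[algo]] <- data.frame(algorithm = algo, feature = sel$selected)
  message(sprintf("%s: %d features selected, CV accuracy %.3f, hold-out %.3f",
                  toupper(algo), length(sel$selected), cv$metrics$accuracy,
                  hold$metrics$accuracy))
}
write.csv(do.call(rbind, rows), "results/cv_metrics.csv", row.names = FALSE)
write.csv(do.call(rbind, hold_rows), "results/holdout_metrics.csv", row.names = FALSE)
write.csv(do.call(rbind, sel_rows), "results/selected_features.csv", row.names = FALSE)

mc <- mcnemar_test(models$svm$cv$predictions, models$ann$cv$predictions, y[train])
message(sprintf("McNemar on CV predictions: b = %d, c = %d, p = %.4f (%s)",
                mc$b, mc$c, mc$p_value, mc$method))
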