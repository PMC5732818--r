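#' Pipeline configuration
#'
#' One object drives the whole analysis: cohort source (a [cohort_spec()] or
#' a case directory), preprocessing parameters, ICC threshold, train/test
#' split sizes, classifier settings and the output directory. All randomness
#' derives from `seed`, expanded into per-stage child seeds.
#'
#' @param cohort A [cohort_spec()] (synthetic mode) or a directory path
#'   (directory mode, as written by [write_cohort()]).
#' @param out_dir Directory for persisted intermediates and the report.
#' @param target_spacing,k_bits Preprocessing parameters.
#' @param icc_threshold Reproducibility threshold.
#' @param n_test Hold-out test size (stratified).
#' @param max_wrapper_features Cap on features entering wrapper selection
#'   (pre-ranked by training-split Kruskal-Wallis p).
#' @param n_folds CV folds.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), out_dir = tempfile("crtrad_"),
                            target_spacing = c(1, 1, 1), k_bits = 4L,
                            icc_threshold = 0.8, n_test = 12L,
                            max_wrapper_features = 15L, n_folds = 10L,
                            seed = 1L) {
  structure(list(cohort = cohort, out_dir = out_dir,
                 target_spacing = target_spacing, k_bits = as.integer(k_bits),
                 icc_threshold = icc_threshold, n_test = as.integer(n_test),
                 max_wrapper_features = as.integer(max_wrapper_features),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

write_table_deterministic <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end radiomics analysis
#'
#' Stages, in order: cohort synthesis (or ingestion), per-observer 214-feature
#' extraction, inter-observer ICC filtering, univariate screening
#' (Kruskal-Wallis + ROC on the whole cohort), stratified train/test split,
#' per-algorithm wrapper feature selection on the training split, 10-fold CV
#' of the SVM and ANN models, McNemar comparison of their out-of-fold
#' predictions, and hold-out validation. Every intermediate is persisted as
#' CSV/JSON under `config$out_dir`; reruns under the same config are
#' byte-identical. If the ICC filter keeps no features, downstream stages are
#' skipped with an explanatory status.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage summaries.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ec <- extract_config(config$target_spacing, config$k_bits)
  report <- list(config = list(seed = config$seed, k_bits = config$k_bits,
                               icc_threshold = config$icc_threshold,
                               n_test = config$n_test,
                               n_folds = config$n_folds,
                               max_wrapper_features = config$max_wrapper_features))

  # --- cohort -------------------------------------------------------------
  cases <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    read_case_directory(config$cohort)
  }
  labels <- vapply(cases, `[[`, "", "label")
  responder <- vapply(cases, `[[`, TRUE, "responder")
  report$cohort <- list(n = length(cases),
                        n_responders = sum(responder),
                        n_nonresponders = sum(!responder),
                        labels = table(labels))

  # --- feature extraction, both observers ---------------------------------
  has_obs2 <- vapply(cases, function(cs) !is.null(cs$mask_secondary), TRUE)
  tab1 <- extract_cohort(cases, ec, observer = 1L)
  write_table_deterministic(tab1, file.path(config$out_dir, "features_obs1.csv"))
  tab2 <- extract_cohort(cases[has_obs2], ec, observer = 2L)
  write_table_deterministic(tab2, file.path(config$out_dir, "features_obs2.csv"))
  manifest <- feature_manifest()
  report$features <- list(n_features = ncol(tab1) - 1L,
                          by_family = table(manifest$family),
                          by_dimensionality = table(manifest$dimensionality),
                          n_cases_with_second_observer = sum(has_obs2))

  # --- reproducibility filter ---------------------------------------------
  icc <- filter_reproducible(tab1[has_obs2, , drop = FALSE], tab2,
                             config$icc_threshold, manifest)
  write_table_deterministic(icc$results, file.path(config$out_dir, "icc_report.csv"))
  report$icc <- list(threshold = config$icc_threshold,
                     n_kept = length(icc$kept),
                     n_dropped = nrow(icc$results) - length(icc$kept),
                     by_family = icc$by_family)
  if (length(icc$kept) == 0) {
    report$status <- "stopped_after_icc: no reproducible features at this threshold"
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(structure(report, class = "run_report"))
  }
  kept_tab <- tab1[, c("case_id", icc$kept), drop = FALSE]

  # --- univariate screening (whole cohort) --------------------------------
  screen <- univariate_screen(kept_tab, labels)
  write_table_deterministic(screen$contrasts,
                            file.path(config$out_dir, "screen_contrasts.csv"))
  roc_tab <- do.call(rbind, lapply(screen$roc, function(r)
    data.frame(feature = r$feature_name, p_value = r$p_value, se = r$se,
               ci_low = r$ci95[1], ci_high = r$ci95[2], auc = r$auc,
               cutoff = paste0(r$side, signif(r$cutoff, 6)),
               sensitivity = r$sensitivity, specificity = r$specificity)))
  if (is.null(roc_tab)) roc_tab <- data.frame()
  write_table_deterministic(roc_tab, file.path(config$out_dir, "screen_roc.csv"))
  report$screen <- list(n_significant = length(screen$significant),
                        significant = screen$significant,
                        group_sizes = screen$group_sizes)

  # --- split, wrapper selection, models -----------------------------------
  split <- make_split(responder, config$n_test, child_seed(config$seed, 31L))
  report$split <- list(n_train = length(split$train), n_test = length(split$test),
                       train_responders = sum(responder[split$train]),
                       test_responders = sum(responder[split$test]))
  train_tab <- kept_tab[split$train, , drop = FALSE]
  y_train <- responder[split$train]

  # univariate pre-ranking cap before the backward search
  p_train <- vapply(icc$kept, function(f)
    kruskal_wallis(train_tab[[f]], ifelse(y_train, "R", "NR"))$p_value, numeric(1))
  top <- icc$kept[order(p_train)][seq_len(min(config$max_wrapper_features,
                                              length(icc$kept)))]
  top <- top[order(match(top, manifest$name))]  # manifest order
  wrap_tab <- train_tab[, c("case_id", top), drop = FALSE]

  models <- list()
  for (algo in c("svm", "ann")) {
    cfg <- model_config(algo, n_folds = config$n_folds,
                        seed = child_seed(config$seed, 41L))
    sel <- wrapper_select(wrap_tab, y_train, cfg)
    sel_tab <- train_tab[, c("case_id", sel$selected), drop = FALSE]
    cv <- cross_validate(sel_tab, y_train, cfg)
    fit <- train_classifier(sel_tab, y_train, cfg)
    hold <- evaluate_holdout(fit, kept_tab[split$test, c("case_id", sel$selected),
                                           drop = FALSE],
                             responder[split$test])
    models[[algo]] <- list(config = cfg, selected = sel$selected,
                           selection_accuracy = sel$best_accuracy,
                           cv = cv, fit = fit, holdout = hold)
  }

  metrics_row <- function(m) {
    unlist(m[c("tp_rate", "fp_rate", "precision", "accuracy", "f_measure",
               "mcc", "auc")])
  }
  cv_metrics <- rbind(svm = metrics_row(models$svm$cv$metrics),
                      ann = metrics_row(models$ann$cv$metrics))
  holdout_metrics <- rbind(svm = metrics_row(models$svm$holdout$metrics),
                           ann = metrics_row(models$ann$holdout$metrics))
  write_table_deterministic(data.frame(algorithm = rownames(cv_metrics), cv_metrics),
                            file.path(config$out_dir, "cv_metrics.csv"))
  write_table_deterministic(data.frame(algorithm = rownames(holdout_metrics),
                                       holdout_metrics),
                            file.path(config$out_dir, "holdout_metrics.csv"))

  mcn <- mcnemar_test(models$svm$cv$predictions, models$ann$cv$predictions,
                      y_train)
  report$models <- list(
    selected = list(svm = models$svm$selected, ann = models$ann$selected),
    cv_metrics = as.data.frame(cv_metrics),
    holdout_metrics = as.data.frame(holdout_metrics),
    mcnemar = mcn,
    holdout_confusion = list(svm = models$svm$holdout$metrics$confusion,
                             ann = models$ann$holdout$metrics$confusion))
  report$status <- "complete"
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  structure(c(report, list(model_objects = models, split_indices = split)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$status %||% "", "\n")
  cat(sprintf("  cohort: %d cases (%d responders / %d nonresponders)\n",
              x$cohort$n, x$cohort$n_responders, x$cohort$n_nonresponders))
  cat(sprintf("  features: %d; ICC-kept: %d; univariately significant: %d\n",
              x$features$n_features, x$icc$n_kept, x$screen$n_significant %||% 0L))
  if (!is.null(x$models)) {
    cat(sprintf("  CV accuracy: SVM %.3f, ANN %.3f (McNemar p = %.3g)\n",
                x$models$cv_metrics["svm", "accuracy"],
                x$models$cv_metrics["ann", "accuracy"],
                x$models$mcnemar$p_value))
    cat(sprintf("  hold-out accuracy: SVM %.3f, ANN %.3f\n",
                x$models$holdout_metrics["svm", "accuracy"],
                x$models$holdout_metrics["ann", "accuracy"]))
  }
  invisible(x)
}
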