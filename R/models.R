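#' Model configuration
#'
#' @param algorithm "svm" (RBF soft-margin, C = 1, gamma = 1/n_features) or
#'   "ann" (single-hidden-layer perceptron with logistic activation,
#'   `ceiling((n_features + 2)/2)` hidden units, seeded initialization,
#'   bounded iterations).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Seed controlling fold assignment and ANN initialization.
#' @param maxit ANN iteration cap.
#' @return A `model_config`.
#' @export
model_config <- function(algorithm = c("svm", "ann"), n_folds = 10L,
                         seed = 1L, maxit = 200L) {
  structure(list(algorithm = match.arg(algorithm),
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed), maxit = as.integer(maxit)),
            class = "model_config")
}

# feature matrix from a table (drops case_id), cases x features
feature_matrix <- function(table) {
  as.matrix(table[setdiff(names(table), "case_id")])
}

#' Train a classifier on standardized features
#'
#' Standardizes features by z-score using the training statistics (stored in
#' the model so held-out cases are standardized identically), then fits the
#' configured algorithm. Both algorithms expose class predictions and a
#' continuous score for ROC analysis via [predict_classifier()].
#'
#' @param table Feature table (or matrix) of the training cases.
#' @param labels Logical (TRUE = positive class, here: responder) per case.
#' @param config A [model_config()].
#' @return A `fitted_classifier`.
#' @export
train_classifier <- function(table, labels, config = model_config()) {
  x <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  y <- as.logical(labels)
  if (sum(y) < 2 || sum(!y) < 2) stopf("need at least 2 cases per class")
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  fac <- factor(y, levels = c(FALSE, TRUE))
  fit <- if (config$algorithm == "svm") {
    e1071::svm(xs, fac, kernel = "radial", cost = 1,
               gamma = 1 / ncol(xs), scale = FALSE)
  } else {
    withr::with_seed(config$seed, {
      nnet::nnet(xs, matrix(as.numeric(y), ncol = 1),
                 size = ceiling((ncol(xs) + 2) / 2),
                 entropy = TRUE, maxit = config$maxit,
                 trace = FALSE, MaxNWts = 100000)
    })
  }
  structure(list(config = config, fit = fit, mu = mu, sdv = sdv,
                 features = colnames(x)),
            class = "fitted_classifier")
}

#' Predict classes and continuous scores
#'
#' @param model A [train_classifier()] fit.
#' @param table Feature table/matrix with the model's features.
#' @return List with `class` (logical) and `score` (numeric; higher = more
#'   positive-class-like).
#' @export
predict_classifier <- function(model, table) {
  x <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  x <- x[, model$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$mu), 2, model$sdv, `/`)
  if (model$config$algorithm == "svm") {
    pr <- predict(model$fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- dv[, 1]
    if (grepl("^FALSE", colnames(dv)[1])) score <- -score  # orient to TRUE
    list(class = pr == "TRUE", score = as.numeric(score))
  } else {
    score <- as.numeric(predict(model$fit, xs))
    list(class = score >= 0.5, score = score)
  }
}

#' Matthews correlation coefficient of a 2x2 confusion matrix
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; any zero factor in
#' the denominator yields 0.
#'
#' @param tp,tn,fp,fn Nonnegative counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Support-weighted per-class metrics from pooled predictions, the reporting
# style where weighted TP-rate, FP-rate, precision and F-measure accompany
# accuracy, MCC and AUC.
classification_metrics <- function(truth, pred, score = NULL) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred); tn <- sum(!truth & !pred)
  fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  per_class <- function(pos) {
    t <- if (pos) truth else !truth
    p <- if (pos) pred else !pred
    tpr <- if (sum(t) > 0) sum(t & p) / sum(t) else 0
    fpr <- if (sum(!t) > 0) sum(!t & p) / sum(!t) else 0
    prec <- if (sum(p) > 0) sum(t & p) / sum(p) else 0
    f <- if (prec + tpr > 0) 2 * prec * tpr / (prec + tpr) else 0
    c(tpr = tpr, fpr = fpr, precision = prec, f = f, support = sum(t))
  }
  a <- per_class(TRUE); b <- per_class(FALSE)
  w <- c(a["support"], b["support"]) / length(truth)
  list(tp_rate = sum(w * c(a["tpr"], b["tpr"])),
       fp_rate = sum(w * c(a["fpr"], b["fpr"])),
       precision = sum(w * c(a["precision"], b["precision"])),
       accuracy = (tp + tn) / length(truth),
       f_measure = sum(w * c(a["f"], b["f"])),
       mcc = mcc(tp, tn, fp, fn),
       auc = if (!is.null(score) && length(unique(truth)) == 2)
         auc_mw(score, truth) else NA_real_,
       confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                          dimnames = list(truth = c("pos", "neg"),
                                          pred = c("pos", "neg"))))
}

# Stratified fold assignment: class ratio preserved within +/- 1 per fold.
stratified_folds <- function(labels, n_folds, seed) {
  y <- as.logical(labels)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Pools out-of-fold predictions and scores over all folds, then computes
#' support-weighted TP-rate, FP-rate, precision and F-measure, pooled
#' accuracy, MCC from the pooled confusion matrix, and AUC from the pooled
#' scores.
#'
#' @param table Feature table of the training cases.
#' @param labels Logical (responder) per case.
#' @param config A [model_config()].
#' @param folds Optional precomputed fold assignment (integers 1..n_folds).
#' @return List: `metrics` (as [classification_metrics()]), `predictions`
#'   (logical), `scores`, `folds`.
#' @export
cross_validate <- function(table, labels, config = model_config(),
                           folds = NULL) {
  y <- as.logical(labels)
  if (is.null(folds)) folds <- stratified_folds(y, config$n_folds, config$seed)
  pred <- logical(length(y)); score <- numeric(length(y))
  x <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) stopf("fold %d leaves a one-class training set", f)
    m <- train_classifier(x[tr, , drop = FALSE], y[tr], config)
    pr <- predict_classifier(m, x[!tr, , drop = FALSE])
    pred[!tr] <- pr$class; score[!tr] <- pr$score
  }
  list(metrics = classification_metrics(y, pred, score),
       predictions = pred, scores = score, folds = folds)
}

#' Wrapper-based backward feature elimination
#'
#' Starting from all features, repeatedly drops the feature whose removal
#' maximizes the classifier's k-fold CV accuracy (ties drop the
#' later-manifest feature), and returns the subset with the best CV accuracy
#' encountered along the path (ties prefer the smaller subset). Fold
#' assignment is fixed by the config seed for the whole search.
#'
#' @param table Feature table (training split only).
#' @param labels Logical (responder) per case.
#' @param config A [model_config()].
#' @param verbose Print the elimination path.
#' @return List: `selected` (feature names in manifest order),
#'   `best_accuracy`, `path` (data.frame of subset size and CV accuracy).
#' @export
wrapper_select <- function(table, labels, config = model_config(),
                           verbose = FALSE) {
  x <- feature_matrix(table)
  y <- as.logical(labels)
  folds <- stratified_folds(y, config$n_folds, config$seed)
  cv_acc <- function(cols) {
    cross_validate(x[, cols, drop = FALSE], y, config, folds)$metrics$accuracy
  }
  current <- colnames(x)
  best <- list(set = current, acc = cv_acc(current))
  path <- data.frame(size = length(current), accuracy = best$acc)
  while (length(current) > 1) {
    accs <- vapply(seq_along(current), function(i)
      cv_acc(setdiff(current, current[i])), numeric(1))
    drop_i <- max(which(accs == max(accs)))   # tie: drop the later feature
    current <- current[-drop_i]
    acc <- accs[drop_i]
    path <- rbind(path, data.frame(size = length(current), accuracy = acc))
    if (verbose)
      message(sprintf("size %d: CV accuracy %.3f", length(current), acc))
    if (acc >= best$acc) best <- list(set = current, acc = acc)  # ties: smaller
  }
  list(selected = best$set, best_accuracy = best$acc, path = path)
}

#' McNemar test on paired classifier predictions
#'
#' Counts discordant cases (`b`: model A correct / B wrong, `c`: A wrong /
#' B correct) and tests symmetric discordance: exact two-sided binomial
#' when `b + c < 25`, chi-square with continuity correction otherwise.
#' Applied to out-of-fold CV predictions when comparing CV performance.
#'
#' @param preds_a,preds_b Logical prediction vectors over the same cases.
#' @param labels True logical labels.
#' @return List: `b`, `c`, `p_value`, `method`.
#' @export
mcnemar_test <- function(preds_a, preds_b, labels) {
  stopifnot(length(preds_a) == length(preds_b),
            length(preds_a) == length(labels))
  ca <- preds_a == labels; cb <- preds_b == labels
  b <- sum(ca & !cb); cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0) return(list(b = b, c = cc, p_value = 1, method = "exact"))
  if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    list(b = b, c = cc, p_value = p, method = "exact")
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    list(b = b, c = cc, p_value = pchisq(stat, 1, lower.tail = FALSE),
         method = "chi-square")
  }
}

#' Stratified train/test split
#'
#' @param labels Logical (responder) per case.
#' @param n_test Number of test cases.
#' @param seed Seed.
#' @return List with integer `train` and `test` index vectors; both classes
#'   present in each part.
#' @export
make_split <- function(labels, n_test, seed = 1L) {
  y <- as.logical(labels)
  n <- length(y)
  n_test_pos <- max(1L, round(n_test * mean(y)))
  n_test_neg <- max(1L, n_test - n_test_pos)
  test <- withr::with_seed(seed, c(sample(which(y), n_test_pos),
                                   sample(which(!y), n_test_neg)))
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Evaluate a trained model on the hold-out split
#'
#' Applies the model (with its stored training standardization) to untouched
#' test cases and reports the same metric set as [cross_validate()] plus the
#' confusion matrix.
#'
#' @param model A [train_classifier()] fit (trained on the training split
#'   only).
#' @param table Feature table of the test cases.
#' @param labels Logical (responder) for the test cases.
#' @return List: `metrics`, `predictions`, `scores`.
#' @export
evaluate_holdout <- function(model, table, labels) {
  x <- if (is.data.frame(table)) feature_matrix(table) else as.matrix(table)
  if (!all(model$features %in% colnames(x)))
    stopf("test table is missing model features")
  if (anyNA(x)) stopf("test cases have missing feature values")
  pr <- predict_classifier(model, x)
  list(metrics = classification_metrics(labels, pr$class, pr$score),
       predictions = pr$class, scores = pr$score)
}
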