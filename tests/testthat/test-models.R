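test_that("MCC worked fixtures", {
  expect_equal(mcc(tp = 5, tn = 5, fp = 0, fn = 0), 1)
  expect_equal(mcc(tp = 0, tn = 0, fp = 5, fn = 5), -1)
  expect_equal(mcc(tp = 3, tn = 2, fp = 1, fn = 1),
               (3 * 2 - 1 * 1) / sqrt(4 * 4 * 3 * 3), tolerance = 1e-12)
  expect_equal(round(mcc(3, 2, 1, 1), 3), 0.417)
  expect_equal(mcc(tp = 5, tn = 0, fp = 0, fn = 0), 0)  # zero-factor convention
})

test_that("McNemar exact p matches the binomial closed form", {
  expect_equal(mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE), c(TRUE, TRUE))$p_value, 1)
  # b = 1, c = 5: two-sided exact p = 2 * P(X <= 1 | Bin(6, 1/2)) = 0.21875
  mk <- function(b, cc) {
    n <- b + cc + 2
    labels <- rep(TRUE, n)
    pa <- c(rep(TRUE, b), rep(FALSE, cc), TRUE, FALSE)
    pb <- c(rep(FALSE, b), rep(TRUE, cc), TRUE, FALSE)
    mcnemar_test(pa, pb, labels)
  }
  r15 <- mk(1, 5)
  expect_equal(r15$b, 1); expect_equal(r15$c, 5)
  expect_equal(r15$p_value, 0.21875)
  expect_equal(mk(3, 3)$p_value, 1)  # symmetric discordance
  for (b in 0:5) for (cc in 0:(10 - b)) {
    if (b + cc == 0) next
    want <- min(1, 2 * sum(choose(b + cc, 0:min(b, cc))) / 2^(b + cc))
    expect_equal(mk(b, cc)$p_value, want, tolerance = 1e-12,
                 label = sprintf("b=%d c=%d", b, cc))
  }
})

test_that("both classifiers fit a linearly separable toy set perfectly", {
  withr::with_seed(1, {
    y <- rep(c(TRUE, FALSE), each = 10)
    x <- cbind(f1 = rnorm(20) + 6 * y, f2 = rnorm(20) - 6 * y)
  })
  for (algo in c("svm", "ann")) {
    m <- train_classifier(x, y, model_config(algo, seed = 2))
    pr <- predict_classifier(m, x)
    expect_equal(pr$class, y, label = algo)
    expect_equal(crtradiomics:::auc_mw(pr$score, y), 1, label = algo)
  }
})

test_that("ANN training is deterministic under the config seed", {
  withr::with_seed(3, {
    y <- rep(c(TRUE, FALSE), each = 12)
    x <- matrix(rnorm(24 * 4), 24, dimnames = list(NULL, paste0("f", 1:4)))
    x[y, 1] <- x[y, 1] + 1
  })
  m1 <- train_classifier(x, y, model_config("ann", seed = 9))
  m2 <- train_classifier(x, y, model_config("ann", seed = 9))
  expect_identical(predict_classifier(m1, x)$score,
                   predict_classifier(m2, x)$score)
})

test_that("pooled metrics match confusion-matrix arithmetic", {
  # majority-class predictor on a 26/11 split
  truth <- rep(c(TRUE, FALSE), c(26, 11))
  pred <- rep(TRUE, 37)
  m <- crtradiomics:::classification_metrics(truth, pred)
  expect_equal(m$accuracy, 26 / 37, tolerance = 1e-12)
  expect_equal(m$mcc, 0)
  expect_equal(m$tp_rate, 26 / 37)  # weighted recall equals accuracy
  # printed 2x2 fixture: TP 20, FN 6, FP 3, TN 8
  truth2 <- rep(c(TRUE, FALSE), c(26, 11))
  pred2 <- c(rep(TRUE, 20), rep(FALSE, 6), rep(TRUE, 3), rep(FALSE, 8))
  m2 <- crtradiomics:::classification_metrics(truth2, pred2)
  prec_pos <- 20 / 23; prec_neg <- 8 / 14
  rec_pos <- 20 / 26; rec_neg <- 8 / 11
  expect_equal(m2$accuracy, 28 / 37)
  expect_equal(m2$precision, (26 * prec_pos + 11 * prec_neg) / 37)
  expect_equal(m2$tp_rate, (26 * rec_pos + 11 * rec_neg) / 37)
  expect_equal(m2$fp_rate, (26 * (3 / 11) + 11 * (6 / 26)) / 37)
  f_pos <- 2 * prec_pos * rec_pos / (prec_pos + rec_pos)
  f_neg <- 2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  expect_equal(m2$f_measure, (26 * f_pos + 11 * f_neg) / 37)
  expect_equal(m2$mcc, mcc(20, 8, 3, 6))
  expect_equal(unname(m2$confusion["pos", "pos"]), 20)
})

test_that("stratified folds preserve the class ratio within one case", {
  y <- rep(c(TRUE, FALSE), c(26, 11))
  folds <- crtradiomics:::stratified_folds(y, 10, seed = 4)
  expect_equal(sort(unique(folds)), 1:10)
  for (f in 1:10) {
    expect_lte(sum(y[folds == f]), 3)
    expect_lte(sum(!y[folds == f]), 2)
  }
})

test_that("a perfect planted rule reaches CV accuracy 1 and MCC 1", {
  withr::with_seed(5, {
    y <- rep(c(TRUE, FALSE), c(20, 17))
    x <- cbind(f1 = ifelse(y, 5, -5) + rnorm(37, sd = 0.1),
               f2 = rnorm(37))
  })
  cv <- cross_validate(x, y, model_config("svm", seed = 6))
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$mcc, 1)
  expect_equal(cv$metrics$auc, 1)
})

test_that("wrapper elimination keeps a planted informative feature", {
  hits <- 0
  for (s in 1:10) {
    pf <- planted_feature_table(16, 14, 1, 20, effect = 3, seed = 400 + s)
    sel <- wrapper_select(pf$table, pf$y, model_config("svm", seed = s))
    hits <- hits + ("f01" %in% sel$selected)
  }
  expect_gte(hits, 9)  # >= 90% of seeds
})

test_that("duplicated informative features: at least one survives selection", {
  pf <- planted_feature_table(15, 12, 1, 6, effect = 3, seed = 77)
  tab <- pf$table
  tab$f01_copy <- tab$f01
  sel <- wrapper_select(tab, pf$y, model_config("svm", seed = 8))
  expect_true(any(c("f01", "f01_copy") %in% sel$selected))
  expect_gte(sel$best_accuracy, 0.85)
})

test_that("per-algorithm selection can differ and both are recorded", {
  pf <- planted_feature_table(14, 12, 2, 6, effect = 1.5, seed = 55)
  sel_svm <- wrapper_select(pf$table, pf$y, model_config("svm", seed = 1))
  sel_ann <- wrapper_select(pf$table, pf$y, model_config("ann", seed = 1, maxit = 80))
  expect_true(length(sel_svm$selected) >= 1)
  expect_true(length(sel_ann$selected) >= 1)
  expect_true(is.data.frame(sel_svm$path))
})

test_that("hold-out evaluation is isolated from test labels", {
  pf <- planted_feature_table(14, 10, 2, 4, effect = 2, seed = 21)
  tr <- 1:16; te <- 17:24
  m <- train_classifier(pf$table[tr, -1], pf$y[tr], model_config("svm", seed = 2))
  h1 <- evaluate_holdout(m, pf$table[te, -1], pf$y[te])
  h2 <- evaluate_holdout(m, pf$table[te, -1], rev(pf$y[te]))  # shuffled labels
  expect_identical(h1$predictions, h2$predictions)
  expect_identical(h1$scores, h2$scores)
  # majority predictor arithmetic on a 7/5 test split
  mets <- crtradiomics:::classification_metrics(rep(c(TRUE, FALSE), c(7, 5)),
                                                rep(TRUE, 12))
  expect_equal(mets$accuracy, 7 / 12)
})

test_that("metrics from one pooled confusion matrix are mutually consistent", {
  withr::with_seed(31, {
    truth <- runif(40) < 0.5
    pred <- ifelse(runif(40) < 0.8, truth, !truth)
  })
  m <- crtradiomics:::classification_metrics(truth, pred)
  cm <- m$confusion
  expect_equal(m$accuracy, (cm[1, 1] + cm[2, 2]) / sum(cm))
  expect_equal(m$mcc, mcc(cm[1, 1], cm[2, 2], cm[1, 2], cm[2, 1]))
})
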