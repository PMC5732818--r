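test_that("Kruskal-Wallis reproduces hand rank arithmetic", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) (12 + 75) - 21 = 3.857
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-6)
  expect_equal(kw$p_value, stats::pchisq(kw$statistic, 1, lower.tail = FALSE))
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)),
               list(statistic = 0, p_value = 1))
})

test_that("tie-corrected H matches the direct formula on a worked set", {
  x <- c(1, 2, 2, 3, 3, 3)
  g <- c("a", "a", "b", "b", "a", "b")
  r <- rank(x)
  n <- 6
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(z) sum(z)^2 / length(z))) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  expect_equal(kruskal_wallis(x, g)$statistic, h_raw / corr, tolerance = 1e-10)
})

test_that("Kruskal-Wallis p is invariant under strictly monotone transforms", {
  withr::with_seed(12, {
    x <- rnorm(30)
    g <- sample(c("a", "b", "c"), 30, replace = TRUE)
  })
  p0 <- kruskal_wallis(x, g)$p_value
  expect_equal(kruskal_wallis(exp(x), g)$p_value, p0)
  expect_equal(kruskal_wallis(atan(2 * x + 1), g)$p_value, p0)
})

test_that("AUC equals the pair-counting estimator on random instances", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(6:30, 1)
      y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
      x <- round(rnorm(n), 1)  # ties likely
    })
    expect_equal(crtradiomics:::auc_mw(x, y), bf_auc(x, y))
  }
})

test_that("ROC worked examples: perfect separation and AUC 0.75", {
  r <- roc_analysis(c(0.9, 0.8, 0.7, 0.2, 0.1),
                    c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  r2 <- roc_analysis(c(0.9, 0.4, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)  # oracle: 3 concordant pairs of 4
})

test_that("orientation: systematically higher scores in positives give side '>'", {
  pos_high <- roc_analysis(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(pos_high$side, ">")
  pos_low <- roc_analysis(c(1, 2, 3, 8, 9), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(pos_low$side, "<=")
  expect_gte(pos_low$auc, 0.5)
})

test_that("Youden cut-off is self-consistent under re-thresholding", {
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      y <- rep(c(TRUE, FALSE), c(12, 9))
      x <- rnorm(21) + y * 1.2
    })
    r <- roc_analysis(x, y)
    pred <- if (r$side == ">") x > r$cutoff else x <= r$cutoff
    expect_equal(100 * sum(pred & y) / sum(y), r$sensitivity)
    expect_equal(100 * sum(!pred & !y) / sum(!y), r$specificity)
  }
})

test_that("AUC and DeLong SE/CI agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(55, {
    y <- rep(c(TRUE, FALSE), c(20, 15))
    x <- rnorm(35) + y * 0.8
  })
  r <- roc_analysis(x, y)
  pr <- pROC::roc(response = y, predictor = x, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_equal(r$se, sqrt(pROC::var(pr)), tolerance = 1e-8)
})

test_that("DeLong test: identical and rank-equivalent scores are degenerate", {
  withr::with_seed(7, {
    y <- rep(c(TRUE, FALSE), c(10, 8))
    x <- rnorm(18) + y
  })
  same <- delong_test(x, x, y)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  mono <- delong_test(x, exp(x) + 3, y)   # rank-preserving transform
  expect_equal(mono$auc_a, mono$auc_b)    # AUC is rank-based
})

test_that("DeLong z and p agree with pROC's paired test", {
  skip_if_not_installed("pROC")
  withr::with_seed(77, {
    y <- rep(c(TRUE, FALSE), c(25, 18))
    a <- rnorm(43) + y * 1.0
    b <- 0.6 * a + rnorm(43, sd = 0.8)
  })
  got <- delong_test(a, b, y)
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                       pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(abs(got$z), abs(as.numeric(pr$statistic)), tolerance = 1e-8)
  expect_equal(got$p_value, as.numeric(pr$p.value), tolerance = 1e-8)
})

test_that("DeLong p agrees with a case-resampling bootstrap on a 49-case cohort", {
  withr::with_seed(91, {
    y <- rep(c(TRUE, FALSE), c(33, 16))
    a <- rnorm(49) + y * 0.9
    b <- rnorm(49) + y * 0.5
  })
  got <- delong_test(a, b, y)
  boots <- withr::with_seed(92, vapply(1:10000, function(i) {
    idx <- c(sample(which(y), replace = TRUE), sample(which(!y), replace = TRUE))
    crtradiomics:::auc_mw(a[idx], y[idx]) - crtradiomics:::auc_mw(b[idx], y[idx])
  }, numeric(1)))
  d <- got$auc_a - got$auc_b
  p_boot <- 2 * stats::pnorm(-abs(d) / stats::sd(boots))
  expect_lt(abs(got$p_value - p_boot), 0.02)
})

test_that("screening finds a planted discriminative feature first", {
  pf <- planted_feature_table(33, 16, 1, 19, effect = 1.2, seed = 5)
  labels <- c(rep(c("CR", "PR"), length.out = 33), rep("SD", 16))
  scr <- univariate_screen(pf$table, labels)
  expect_equal(scr$significant[1], "f01")
  expect_lt(scr$contrasts[scr$contrasts$feature == "f01",
                          "responders_vs_nonresponders"], 0.05)
  expect_equal(unname(scr$group_sizes), c(33, 16))
  # all three contrasts present with p-values in [0, 1]
  expect_named(scr$contrasts,
               c("feature", "responders_vs_nonresponders", "SD_vs_PR", "SD_vs_CR"))
  expect_true(all(scr$contrasts[, -1] >= 0 & scr$contrasts[, -1] <= 1))
  # ROC orientation: responders carry higher values of f01, so with the
  # nonresponder-positive convention the cut-off side is "<="
  expect_equal(scr$roc[["f01"]]$side, "<=")
})

test_that("screening warns and continues when a contrast has no cases", {
  pf <- planted_feature_table(6, 4, 1, 2, effect = 2, seed = 6)
  labels <- c(rep("CR", 6), rep("SD", 4))  # no PR cases at all
  expect_warning(scr <- univariate_screen(pf$table, labels), "SD_vs_PR")
  expect_true(all(is.na(scr$contrasts$SD_vs_PR)))
  expect_false(anyNA(scr$contrasts$SD_vs_CR))
})
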