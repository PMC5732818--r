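#' Two-way single-measure absolute-agreement ICC
#'
#' Intraclass correlation for two fixed raters scoring the same cases:
#' two-way mixed-effects model, single measure, absolute agreement
#' (ICC(A,1)), computed from the mean-square decomposition
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with n cases and
#' k raters. A table with zero total variance is perfect trivial agreement
#' and returns 1 (with attribute `degenerate = TRUE`).
#'
#' @param ratings Numeric matrix, n cases x k raters (k = 2 for two
#'   observers); n >= 3.
#' @return ICC value in \[-1, 1\].
#' @export
icc_two_way <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stopf("ICC needs at least 3 cases")
  if (!all(is.finite(ratings))) stopf("ICC ratings must be finite")
  grand <- mean(ratings)
  if (sum((ratings - grand)^2) <= .Machine$double.eps * max(1, grand^2) * n * k)
    return(structure(1, degenerate = TRUE))
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Filter features by inter-observer reproducibility
#'
#' Computes the two-rater ICC of every feature across cases and keeps those
#' with ICC at or above the threshold, preserving manifest order.
#'
#' @param table_obs1,table_obs2 Feature tables from [extract_cohort()] for
#'   observers 1 and 2 (same cases, same columns).
#' @param threshold Reproducibility threshold (default 0.8).
#' @param manifest Feature manifest for family grouping.
#' @return List with `kept` (character vector of feature names), `results`
#'   (data.frame: feature, family, icc, reproducible) and `by_family`
#'   (counts of non-reproducible features per family).
#' @export
filter_reproducible <- function(table_obs1, table_obs2, threshold = 0.8,
                                manifest = feature_manifest()) {
  if (!identical(table_obs1$case_id, table_obs2$case_id))
    stopf("observer tables disagree on cases")
  feats <- intersect(manifest$name, names(table_obs1))
  if (!identical(sort(feats), sort(intersect(manifest$name, names(table_obs2)))))
    stopf("observer tables disagree on features")
  icc <- vapply(feats, function(f)
    as.numeric(icc_two_way(cbind(table_obs1[[f]], table_obs2[[f]]))), numeric(1))
  res <- data.frame(feature = feats,
                    family = manifest$family[match(feats, manifest$name)],
                    icc = icc,
                    reproducible = icc >= threshold)
  by_family <- stats::aggregate(reproducible ~ family, res,
                                function(z) sum(!z))
  names(by_family)[2] <- "n_below_threshold"
  list(kept = res$feature[res$reproducible], results = res,
       by_family = by_family, threshold = threshold)
}
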