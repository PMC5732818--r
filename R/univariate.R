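#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on (groups - 1)
#' degrees of freedom (a thin wrapper over [stats::kruskal.test()], the
#' reference implementation of the rank arithmetic). Identical values across
#' all groups return H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 nonempty groups).
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need at least two nonempty groups")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(values, droplevels(groups))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

# Mann-Whitney AUC of `scores` for the `positive` logical class:
# P(score_pos > score_neg) + 0.5 P(equal), by pair counting via ranks.
auc_mw <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement-value components for one score vector.
delong_placements <- function(scores, positive) {
  x <- scores[positive]; y <- scores[!positive]
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / length(y),
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / length(x),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

delong_se <- function(scores, positive) {
  pl <- delong_placements(scores, positive)
  s10 <- if (length(pl$v10) > 1) var(pl$v10) else 0
  s01 <- if (length(pl$v01) > 1) var(pl$v01) else 0
  sqrt(s10 / length(pl$v10) + s01 / length(pl$v01))
}

#' ROC analysis of one feature
#'
#' AUC by the Mann-Whitney pair-counting estimator (ties count 1/2),
#' oriented so AUC >= 0.5 with the orientation recorded as the cut-off side
#' (`">"` when high scores mark the positive class, `"<="` otherwise);
#' standard error by the DeLong variance; 95% CI = AUC +/- 1.96 SE clipped to
#' \[0, 1\]; the optimal cut-off maximizes Youden's J over observed-score
#' midpoints (ties broken toward higher sensitivity); p-value from the
#' normal test of AUC = 0.5.
#'
#' @param scores Numeric feature values.
#' @param labels Logical (TRUE = positive class) or two-level factor whose
#'   second level is taken as positive.
#' @param feature_name Optional name carried into the result.
#' @return An object of class `roc_result`: `auc`, `se`, `ci95`, `cutoff`,
#'   `side`, `sensitivity`, `specificity` (percent), `p_value`.
#' @export
roc_analysis <- function(scores, labels, feature_name = NA_character_) {
  positive <- if (is.logical(labels)) labels else factor(labels) == levels(factor(labels))[2]
  if (!any(positive) || all(positive)) stopf("both classes must be present")
  auc_raw <- auc_mw(scores, positive)
  side <- if (auc_raw >= 0.5) ">" else "<="
  oriented <- if (side == ">") scores else -scores
  auc <- auc_mw(oriented, positive)
  se <- delong_se(oriented, positive)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * se))
  # Youden cut-off over midpoints of adjacent sorted unique scores
  u <- sort(unique(oriented))
  cand <- if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2 else u
  best <- NULL
  for (ct in cand) {
    pred <- oriented > ct
    sens <- sum(pred & positive) / sum(positive)
    spec <- sum(!pred & !positive) / sum(!positive)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens)) {
      best <- list(cut = ct, j = j, sens = sens, spec = spec)
    }
  }
  cutoff <- if (side == ">") best$cut else -best$cut
  structure(list(feature_name = feature_name, auc = auc, se = se,
                 ci95 = ci, cutoff = cutoff, side = side,
                 sensitivity = 100 * best$sens, specificity = 100 * best$spec,
                 p_value = p),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result %s> AUC %.3f (SE %.4f, 95%% CI %.3f-%.3f), cut-off %s%.4g, sens %.1f%%, spec %.1f%%, p = %.4g\n",
              x$feature_name %||% "", x$auc, x$se, x$ci95[1], x$ci95[2],
              x$side, x$cutoff, x$sensitivity, x$specificity, x$p_value))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors over the same cases,
#' using the DeLong placement-value covariance structure; two-sided normal
#' p-value. A zero-variance AUC difference (e.g. identical or rank-equivalent
#' scores) returns p = 1 with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Numeric score vectors over the same cases.
#' @param labels Logical positive-class indicator (or two-level factor).
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  positive <- if (is.logical(labels)) labels else factor(labels) == levels(factor(labels))[2]
  if (length(scores_a) != length(scores_b)) stopf("score vectors must be paired")
  pa <- delong_placements(scores_a, positive)
  pb <- delong_placements(scores_b, positive)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0,
                p_value = 1, degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Univariate screening of a feature table
#'
#' Runs three Kruskal-Wallis contrasts per feature — responders (CR + PR) vs
#' nonresponders (SD), SD vs PR, SD vs CR — and ROC analysis (nonresponder
#' as positive class, matching the convention that high-skewness tumors mark
#' nonresponders) for features significant in the main contrast. Raw
#' p-values are reported; no multiple-testing correction is applied.
#'
#' @param table Feature table (`case_id` + feature columns), typically the
#'   reproducible subset.
#' @param labels Character vector of CR/PR/SD/PD per case.
#' @param alpha Significance threshold for the main contrast (default 0.05).
#' @return List with `contrasts` (data.frame feature x contrast p-values),
#'   `significant` (features with main-contrast p < alpha, sorted by p) and
#'   `roc` (named list of `roc_result` for the significant features).
#' @export
univariate_screen <- function(table, labels, alpha = 0.05) {
  feats <- setdiff(names(table), "case_id")
  responder <- labels %in% c("CR", "PR")
  contrasts <- list(
    responders_vs_nonresponders = list(sel = rep(TRUE, length(labels)),
                                       grp = ifelse(responder, "R", "NR")),
    SD_vs_PR = list(sel = labels %in% c("SD", "PR"), grp = labels),
    SD_vs_CR = list(sel = labels %in% c("SD", "CR"), grp = labels))
  pmat <- matrix(NA_real_, length(feats), length(contrasts),
                 dimnames = list(feats, names(contrasts)))
  for (ci in seq_along(contrasts)) {
    sel <- contrasts[[ci]]$sel
    grp <- contrasts[[ci]]$grp[sel]
    if (length(unique(grp)) < 2 || length(grp) == 0) {
      warning(sprintf("contrast %s has an empty class; skipped",
                      names(contrasts)[ci]))
      next
    }
    for (f in feats)
      pmat[f, ci] <- kruskal_wallis(table[[f]][sel], grp)$p_value
  }
  main_p <- pmat[, 1]
  sig <- names(sort(main_p[!is.na(main_p) & main_p < alpha]))
  roc <- lapply(sig, function(f)
    roc_analysis(table[[f]], !responder, feature_name = f))
  names(roc) <- sig
  list(contrasts = data.frame(feature = feats, pmat, check.names = FALSE),
       significant = sig, roc = roc,
       group_sizes = c(responders = sum(responder),
                       nonresponders = sum(!responder)))
}
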