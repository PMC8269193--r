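## Screening evaluation: ROC/AUC with DeLong variance and paired tests,
## sensitivity and threshold percentile at fixed false-positive rates,
## two-proportion comparisons and logistic odds ratios.
##
## Score convention throughout: a LOWER estimated percentile weight is more
## SGA-like, and a record screens positive when its percentile lies
## strictly BELOW the threshold (one strictness rule, matching the "below
## the 10th percentile" definition of SGA itself).

## DeLong structural components.  Scores are negated internally so that an
## AUC above 0.5 means low percentiles discriminate the positive class.
delong_components <- function(percentiles, labels) {
  stopifnot(length(percentiles) == length(labels))
  keep <- !is.na(percentiles) & !is.na(labels)
  percentiles <- percentiles[keep]
  labels <- as.logical(labels[keep])
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0 || n == 0) {
    stop("AUC is undefined: need at least one positive and one negative")
  }
  s <- -percentiles
  x <- s[labels]
  y <- s[!labels]
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n        # P(score > random negative)
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong confidence interval
#'
#' Tie-aware Mann-Whitney AUC of the estimated percentile weight for
#' discriminating an outcome, with variance from DeLong's structural
#' components estimator and a Wald 95% CI clamped to \[0, 1\].  Lower
#' percentiles are treated as more outcome-like.
#'
#' @param percentiles numeric scores (EPW percentiles).
#' @param labels logical outcome (TRUE = case, e.g. SGA at birth).
#' @param conf_level confidence level.
#' @return list with `auc`, `ci_low`, `ci_high`, `se`, `n_pos`, `n_neg`.
#' @export
auc_delong <- function(percentiles, labels, conf_level = 0.95) {
  cmp <- delong_components(percentiles, labels)
  s10 <- if (cmp$m > 1) var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) var(cmp$v01) else 0
  se <- sqrt(s10 / cmp$m + s01 / cmp$n)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(auc = cmp$auc,
       ci_low = clamp(cmp$auc - zq * se, 0, 1),
       ci_high = clamp(cmp$auc + zq * se, 0, 1),
       se = se, n_pos = cmp$m, n_neg = cmp$n)
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided p-value for the difference of the AUCs of two score vectors
#' computed on the same records, using the DeLong covariance of the paired
#' structural components.
#'
#' @param percentiles_a,percentiles_b scores on the same records.
#' @param labels logical outcome vector.
#' @return list with `p_value`, `auc_a`, `auc_b`, `z`.
#' @export
delong_paired_test <- function(percentiles_a, percentiles_b, labels) {
  if (length(percentiles_a) != length(percentiles_b) ||
        length(percentiles_a) != length(labels)) {
    stop("paired DeLong test requires aligned score and label vectors")
  }
  keep <- !is.na(percentiles_a) & !is.na(percentiles_b) & !is.na(labels)
  a <- delong_components(percentiles_a[keep], labels[keep])
  b <- delong_components(percentiles_b[keep], labels[keep])
  d10 <- a$v10 - b$v10
  d01 <- a$v01 - b$v01
  v <- (if (a$m > 1) var(d10) else 0) / a$m + (if (a$n > 1) var(d01) else 0) / a$n
  diff <- a$auc - b$auc
  if (v <= .Machine$double.eps) {
    return(list(p_value = if (abs(diff) < 1e-12) 1 else 0,
                auc_a = a$auc, auc_b = b$auc, z = if (abs(diff) < 1e-12) 0 else Inf))
  }
  z <- diff / sqrt(v)
  list(p_value = 2 * pnorm(-abs(z)), auc_a = a$auc, auc_b = b$auc, z = z)
}

#' Wilson score confidence interval for a binomial proportion
#' @param k successes, `n` trials, `conf_level` confidence level.
#' @param n number of trials.
#' @param conf_level confidence level.
#' @return `c(low, high)` on the proportion scale.
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  ## the interval closes exactly at the boundaries (avoids the point
  ## estimate escaping by a rounding ulp when k = 0 or k = n)
  c(low = if (k == 0) 0 else max(0, centre - half),
    high = if (k == n) 1 else min(1, centre + half))
}

#' Sensitivity and threshold percentile at a fixed false-positive rate
#'
#' The screening threshold is the largest candidate percentile `t` such
#' that the fraction of outcome-negative records with percentile strictly
#' below `t` does not exceed the target FPR; sensitivity is the fraction of
#' outcome-positive records below that threshold.  The achieved FPR (always
#' at or under the target) is reported alongside.
#'
#' @param percentiles EPW percentile scores.
#' @param labels logical outcome vector.
#' @param target_fpr target false-positive rate, percent (0-100].
#' @param conf_level confidence level for the sensitivity CI.
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return list with `sensitivity` (%), `ci_low`, `ci_high` (%),
#'   `threshold_percentile`, `achieved_fpr` (%), `n_pos`, `n_neg`.
#' @export
sensitivity_at_fpr <- function(percentiles, labels, target_fpr,
                               conf_level = 0.95,
                               ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  stopifnot(target_fpr > 0, target_fpr <= 100)
  keep <- !is.na(percentiles) & !is.na(labels)
  percentiles <- percentiles[keep]
  labels <- as.logical(labels[keep])
  m <- sum(labels)
  n <- sum(!labels)
  if (m == 0 || n == 0) {
    stop("sensitivity is undefined: need at least one positive and one negative")
  }
  neg <- percentiles[!labels]
  pos <- percentiles[labels]
  ## Candidate thresholds: every observed score, plus one above the maximum
  ## so a 100% target FPR admits every record.
  cand <- sort(unique(c(percentiles, max(percentiles) + 1)))
  fpr_at <- vapply(cand, function(t) sum(neg < t) / n, numeric(1))
  t_star <- max(cand[fpr_at <= target_fpr / 100])
  k <- sum(pos < t_star)
  sens <- k / m
  ci <- if (ci_method == "wilson") {
    wilson_ci(k, m, conf_level)
  } else {
    zq <- qnorm(1 - (1 - conf_level) / 2)
    half <- zq * sqrt(sens * (1 - sens) / m)
    c(low = max(0, sens - half), high = min(1, sens + half))
  }
  list(sensitivity = 100 * sens,
       ci_low = 100 * ci[["low"]], ci_high = 100 * ci[["high"]],
       threshold_percentile = t_star,
       achieved_fpr = 100 * sum(neg < t_star) / n,
       n_pos = m, n_neg = n)
}

#' Full screening evaluation of one score vector
#'
#' AUC with DeLong CI plus sensitivity, CI, threshold percentile and
#' achieved FPR at each target false-positive rate.
#'
#' @param percentiles EPW percentile scores.
#' @param labels logical outcome vector.
#' @param fprs target FPRs in percent.
#' @param conf_level confidence level.
#' @return list of class `screen_eval`: `auc` (from [auc_delong()]) and
#'   `by_fpr`, a data.frame with one row per target FPR.
#' @export
screen_eval <- function(percentiles, labels, fprs = c(5, 10, 15, 20),
                        conf_level = 0.95) {
  auc <- auc_delong(percentiles, labels, conf_level)
  rows <- lapply(fprs, function(f) {
    s <- sensitivity_at_fpr(percentiles, labels, f, conf_level)
    data.frame(target_fpr = f, sensitivity = s$sensitivity,
               ci_low = s$ci_low, ci_high = s$ci_high,
               threshold_percentile = s$threshold_percentile,
               achieved_fpr = s$achieved_fpr)
  })
  structure(list(auc = auc, by_fpr = do.call(rbind, rows),
                 n_pos = auc$n_pos, n_neg = auc$n_neg),
            class = "screen_eval")
}

#' @export
print.screen_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.3f-%.3f), %d cases / %d non-cases\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high, x$n_pos, x$n_neg))
  df <- x$by_fpr
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  FPR %2.0f%%: sens %5.1f%% (%.1f-%.1f) at threshold pc %.1f (achieved FPR %.1f%%)\n",
                df$target_fpr[i], df$sensitivity[i], df$ci_low[i], df$ci_high[i],
                df$threshold_percentile[i], df$achieved_fpr[i]))
  }
  invisible(x)
}

#' Two-proportion z-test
#'
#' Two-sided pooled-variance z-test for `k1/n1` versus `k2/n2`, with the
#' continuity correction off by default.
#'
#' @param k1,n1,k2,n2 counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `p_value`, `z`, `p1`, `p2`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = FALSE) {
  for (v in list(k1 = k1, n1 = n1, k2 = k2, n2 = n2)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != floor(v)) {
      stop("counts must be single non-negative integers")
    }
  }
  if (n1 == 0 || n2 == 0 || k1 > n1 || k2 > n2) stop("need 0 <= k <= n with n > 0")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    return(list(p_value = 1, z = 0, p1 = p1, p2 = p2))
  }
  d <- abs(p1 - p2)
  if (correct) d <- max(0, d - (1 / n1 + 1 / n2) / 2)
  z <- d / se
  list(p_value = 2 * pnorm(-z), z = z, p1 = p1, p2 = p2)
}

#' Logistic odds ratio per one-point increase in EPW percentile
#'
#' Maximum-likelihood logistic regression of the outcome on the EPW
#' percentile; the reported odds ratio corresponds to a one-percentile
#' increase, with a Wald 95% confidence interval.
#'
#' @param percentiles EPW percentile scores.
#' @param labels logical outcome vector.
#' @param conf_level confidence level.
#' @return list with `or`, `ci_low`, `ci_high`, `slope`, `se`.
#' @export
logistic_or_per_percent <- function(percentiles, labels, conf_level = 0.95) {
  keep <- !is.na(percentiles) & !is.na(labels)
  percentiles <- percentiles[keep]
  labels <- as.logical(labels[keep])
  if (!any(labels) || all(labels)) stop("both outcome classes must be present")
  if (max(percentiles[labels]) < min(percentiles[!labels]) ||
        min(percentiles[labels]) > max(percentiles[!labels])) {
    stop("logistic fit does not converge: complete separation of the classes")
  }
  fit <- glm(labels ~ percentiles, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge")
  slope <- coef(fit)[["percentiles"]]
  se <- sqrt(vcov(fit)["percentiles", "percentiles"])
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(slope), ci_low = exp(slope - zq * se),
       ci_high = exp(slope + zq * se), slope = slope, se = se)
}
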