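## Independent oracles and small fixtures used across the suite.

## Exhaustive concordant-pair count (ties half) for the AUC of a score
## where LOWER values indicate the positive class.
brute_force_auc <- function(percentiles, labels) {
  pos <- percentiles[labels]
  neg <- percentiles[!labels]
  pairs <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  sum(pairs) / (length(pos) * length(neg))
}

## Exhaustive threshold scan matching the screening contract: candidate
## thresholds are all observed scores plus one above the maximum; pick the
## largest whose strict-below FPR does not exceed the target.
brute_force_sensitivity <- function(percentiles, labels, target_fpr) {
  pos <- percentiles[labels]
  neg <- percentiles[!labels]
  cand <- sort(unique(c(percentiles, max(percentiles) + 1)))
  best <- NULL
  for (t in cand) {
    if (sum(neg < t) / length(neg) <= target_fpr / 100) best <- t
  }
  list(threshold = best,
       sensitivity = 100 * sum(pos < best) / length(pos),
       achieved_fpr = 100 * sum(neg < best) / length(neg))
}

## Two-proportion pooled z-test written out longhand.
brute_force_two_prop_p <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  2 * stats::pnorm(-abs(z))
}

## Bernoulli log-likelihood of a logistic model.
logistic_loglik <- function(intercept, slope, x, y) {
  eta <- intercept + slope * x
  sum(y * eta - log1p(exp(eta)))
}

## Profile-grid maximizer of the logistic likelihood: a slope grid refined
## three times, with the intercept profiled out by 1-d optimization.
grid_search_logistic_slope <- function(x, y, lo = -2, hi = 2) {
  profile <- function(b) {
    stats::optimize(function(a) -logistic_loglik(a, b, x, y),
                    interval = c(-60, 60))$objective
  }
  for (step in 1:4) {
    grid <- seq(lo, hi, length.out = 81)
    vals <- vapply(grid, profile, numeric(1))
    best <- grid[which.min(vals)]
    half <- (hi - lo) / 80
    lo <- best - 2 * half
    hi <- best + 2 * half
  }
  best
}

## A tiny deterministic z-score standard for engine tests: median 2500 g at
## 246 days growing 1%/day, lognormal sigma 0.12.
toy_zscore_standard <- function(sigma = 0.12, transform = "log", cv = 0.11,
                                ga_range = c(238, 259)) {
  disp <- if (transform == "log") list(transform = "log", sigma_log = sigma)
          else list(transform = "identity", cv = cv)
  growth_standard("toy_z", "zscore_curve", "hadlock4",
                  parameters = list(
                    median_curve = list(w_ref_g = 2500, ga_ref = 246,
                                        b1 = 0.01, b2 = 0),
                    dispersion = disp,
                    ga_range = ga_range))
}

toy_customized_standard <- function() {
  growth_standard("toy_cust", "customized", "hadlock4",
                  parameters = list(
                    base_term_weight_g = 3300,
                    proportionality = list(ga_ref = 280, b1 = 0.0065, b2 = -5.32e-5),
                    dispersion = list(transform = "identity", cv = 0.11),
                    scale = 1,
                    covariate_effects = list(
                      maternal_height = list(type = "linear", ref = 163, per_unit = 8),
                      parity = list(type = "categorical", ref = "0",
                                    effects = list(`1` = 100, `2+` = 140)),
                      sex = list(type = "categorical", ref = "female",
                                 effects = list(male = 120)))))
}

toy_quantile_grid <- function(sigma = 0.12) {
  levels <- c(5, 10, 25, 50, 75, 90, 95)
  ga <- c(238, 245, 252, 259)
  med <- 2500 * exp(0.01 * (ga - 246))
  growth_standard("toy_grid", "quantile_grid", "hadlock4",
                  parameters = list(ga_grid = ga, levels = levels,
                                    weights = outer(med, exp(sigma * qnorm(levels / 100)))))
}

## Small cohort for fast end-to-end tests.
small_cohort_config <- function(n = 400, seed = 99, ...) {
  cohort_config(n_records = n, seed = seed, ...)
}
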