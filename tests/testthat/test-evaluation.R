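test_that("AUC handles separation, ties, and matches exhaustive pair counting", {
  ## perfect separation: all cases below all non-cases
  sep <- auc_delong(c(1, 2, 3, 20, 30, 40), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$ci_high, 1)
  ## tie-degenerate: identical scores
  expect_equal(auc_delong(rep(7, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  ## interleaved 6 + 6 instance against the brute-force pair count
  p <- c(5, 12, 18, 25, 33, 41, 8, 15, 18, 28, 36, 50)
  lab <- rep(c(TRUE, FALSE), each = 6)
  expect_equal(auc_delong(p, lab)$auc, brute_force_auc(p, lab))
  ## single-class input is undefined
  expect_error(auc_delong(1:5, rep(TRUE, 5)), "undefined")
})

test_that("AUC equals exhaustive pair counting on random small instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    m <- sample(seq_len(n - 1), 1)
    lab <- sample(rep(c(TRUE, FALSE), c(m, n - m)))
    p <- sample(1:6, n, replace = TRUE) * 10  # deliberate ties
    expect_equal(auc_delong(p, lab)$auc, brute_force_auc(p, lab))
  }
})

test_that("AUC is invariant under strictly monotone score transforms and CI covers it", {
  set.seed(7)
  p <- runif(200, 0, 100)
  lab <- runif(200) < plogis(-(p - 40) / 10)
  a <- auc_delong(p, lab)
  expect_equal(auc_delong(qnorm(p / 100) * 10 + 50, lab)$auc, a$auc)
  expect_equal(auc_delong(p^3 / 1e4, lab)$auc, a$auc)
  expect_gte(a$se, 0)
  expect_true(a$ci_low <= a$auc && a$auc <= a$ci_high)
})

test_that("paired DeLong test: self-comparison, alignment, bootstrap oracle", {
  set.seed(3)
  p <- runif(40, 0, 100)
  lab <- c(rep(TRUE, 12), rep(FALSE, 28))
  expect_equal(delong_paired_test(p, p, lab)$p_value, 1)
  expect_error(delong_paired_test(p[-1], p, lab), "aligned")

  ## small-instance check against a stratified bootstrap of the AUC
  ## difference (B = 20000): the normal-approximation p must land within
  ## 0.02 of the bootstrap two-sided p.
  set.seed(14)
  n_pos <- 8; n_neg <- 12
  lab2 <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  latent <- c(rnorm(n_pos, -1), rnorm(n_neg))
  a <- 100 * pnorm(latent + rnorm(20, 0, 0.6))
  b <- 100 * pnorm(latent + rnorm(20, 0, 1.4))
  got <- delong_paired_test(a, b, lab2)
  B <- 20000
  diffs <- replicate(B, {
    ip <- sample(n_pos, replace = TRUE)
    im <- n_pos + sample(n_neg, replace = TRUE)
    idx <- c(ip, im)
    brute_force_auc(a[idx], lab2) - brute_force_auc(b[idx], lab2)
  })
  boot_p <- 2 * pnorm(-abs(got$auc_a - got$auc_b) / sd(diffs))
  expect_lt(abs(got$p_value - boot_p), 0.02)
})

test_that("sensitivity at fixed FPR follows the threshold contract", {
  ## separation: every case below every non-case
  s <- sensitivity_at_fpr(c(1:5, 51:60), c(rep(TRUE, 5), rep(FALSE, 10)), 5)
  expect_equal(s$sensitivity, 100)
  ## worked instance: 10 non-cases at 10, 20, ..., 100 and 5 cases at
  ## 5, 15, 25, 35, 45 with a 20% target: the largest admissible threshold
  ## is 30 (2/10 non-cases below), detecting 3/5 cases.
  perc <- c(seq(10, 100, 10), c(5, 15, 25, 35, 45))
  lab <- rep(c(FALSE, TRUE), c(10, 5))
  s2 <- sensitivity_at_fpr(perc, lab, 20)
  expect_equal(s2$threshold_percentile, 30)
  expect_equal(s2$sensitivity, 60)
  expect_equal(s2$achieved_fpr, 20)
  ## a 100% target admits everything
  expect_equal(sensitivity_at_fpr(perc, lab, 100)$sensitivity, 100)
})

test_that("sensitivity equals a brute-force threshold scan on random instances", {
  set.seed(11)
  for (i in 1:80) {
    n <- sample(15:60, 1)
    m <- sample(3:(n %/% 2), 1)
    lab <- sample(rep(c(TRUE, FALSE), c(m, n - m)))
    perc <- round(runif(n, 0, 100), sample(c(0, 1), 1))
    f <- sample(c(5, 10, 15, 20, 35), 1)
    got <- sensitivity_at_fpr(perc, lab, f)
    want <- brute_force_sensitivity(perc, lab, f)
    expect_equal(got$threshold_percentile, want$threshold)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$achieved_fpr, want$achieved_fpr)
    expect_lte(got$achieved_fpr, f)
    expect_true(got$ci_low <= got$sensitivity && got$sensitivity <= got$ci_high)
  }
})

test_that("sensitivity is nondecreasing in the target FPR (screen_eval invariants)", {
  set.seed(23)
  p <- runif(500, 0, 100)
  lab <- runif(500) < plogis(-(p - 30) / 12)
  ev <- screen_eval(p, lab, fprs = c(5, 10, 15, 20))
  expect_true(all(diff(ev$by_fpr$sensitivity) >= 0))
  expect_true(all(diff(ev$by_fpr$threshold_percentile) >= 0))
  expect_true(all(ev$by_fpr$achieved_fpr <= ev$by_fpr$target_fpr))
})

test_that("two-proportion test matches the longhand pooled z formula and prop.test", {
  expect_equal(two_proportion_test(3, 10, 7, 10)$p_value,
               brute_force_two_prop_p(3, 10, 7, 10), tolerance = 1e-6)
  expect_lt(two_proportion_test(174, 645, 51, 645)$p_value, 0.001)
  expect_equal(two_proportion_test(10, 100, 10, 100)$p_value, 1)
  ## z^2 is the chi-square of the uncorrected test
  pt <- suppressWarnings(prop.test(c(35, 20), c(120, 110), correct = FALSE))
  expect_equal(two_proportion_test(35, 120, 20, 110)$p_value, pt$p.value,
               tolerance = 1e-12)
  expect_error(two_proportion_test(5, 4, 1, 10), "0 <= k <= n")
  expect_error(two_proportion_test(0.5, 4, 1, 10), "non-negative integers")
})

test_that("logistic OR per percentile point behaves at the null and matches a grid search", {
  set.seed(19)
  p <- runif(300, 0, 100)
  lab_null <- runif(300) < 0.2
  null_fit <- logistic_or_per_percent(p, lab_null)
  expect_true(null_fit$ci_low <= 1 && 1 <= null_fit$ci_high)
  ## informative case: higher percentile lowers SGA probability -> OR < 1
  lab <- runif(300) < plogis(-(p - 30) / 10)
  expect_lt(logistic_or_per_percent(p, lab)$or, 1)
  ## n = 30 fixture against a profile-grid likelihood maximizer
  set.seed(4)
  x <- round(runif(30, 0, 100), 1)
  y <- runif(30) < plogis(1 - 0.06 * x)
  fit <- logistic_or_per_percent(x, y)
  expect_equal(fit$slope, grid_search_logistic_slope(x, y), tolerance = 1e-4)
  ## complete separation is reported, not silently fitted
  expect_error(logistic_or_per_percent(c(1, 2, 3, 10, 11, 12),
                                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)),
               "separation")
})

test_that("AUC and DeLong CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  p <- runif(250, 0, 100)
  lab <- runif(250) < plogis(-(p - 35) / 15)
  ours <- auc_delong(p, lab)
  ref <- pROC::roc(response = lab, predictor = p, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(ours$ci_low, ours$ci_high), ci[c(1, 3)], tolerance = 1e-9)
})
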