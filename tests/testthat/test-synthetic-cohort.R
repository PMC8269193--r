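test_that("generation is reproducible and size-exact", {
  cfg <- small_cohort_config(n = 300, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 300)
  expect_equal(nrow(generate_cohort(small_cohort_config(n = 0))), 0)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(parity_probs = c(`0` = 0.5, `1` = 0.4, `2+` = 0.2)),
               "parity_probs")
  expect_error(cohort_config(percentile_persistence_rho = 1), "percentile_persistence_rho")
  expect_error(cohort_config(n_records = -1), "n_records")
  expect_error(cohort_config(target_sga_rate = 1.2), "target_sga_rate")
})

test_that("records satisfy the inclusion-window invariants", {
  coh <- generate_cohort(small_cohort_config(n = 500, seed = 5))
  expect_true(all(coh$ga_scan_days >= 238 & coh$ga_scan_days <= 258))
  expect_true(all(coh$ga_delivery_days >= 259 & coh$ga_delivery_days <= 294))
  expect_true(all(coh$ga_delivery_days > coh$ga_scan_days))
  expect_true(all(coh$birthweight_g > 0))
  expect_true(all(coh$bpd_mm > 0 & coh$hc_mm > 0 & coh$ac_mm > 0 & coh$fl_mm > 0))
})

test_that("marginal medians recover the configured targets at n = 5000", {
  cfg <- cohort_config(n_records = 5000, seed = 31)
  coh <- generate_cohort(cfg)
  expect_equal(median(coh$maternal_age), cfg$maternal_age[[1]], tolerance = 0.02)
  expect_equal(median(coh$maternal_bmi), cfg$maternal_bmi[[1]], tolerance = 0.02)
  expect_equal(median(coh$maternal_height), cfg$maternal_height[[1]], tolerance = 0.02)
  expect_equal(median(coh$paternal_height), cfg$paternal_height[[1]], tolerance = 0.02)
  expect_equal(median(coh$birthweight_g),
               curve_median(cfg$delivery_ga_median, cfg$growth_curve),
               tolerance = 0.02)
})

test_that("latent percentile copula: near-unit persistence gives near-unit rank correlation", {
  ## Closed-form check: Spearman's rho of a bivariate normal with rho = 0.99
  ## is (6 / pi) * asin(0.99 / 2) = 0.9886, so the sample value must clear 0.98.
  cfg <- cohort_config(n_records = 5000, seed = 8,
                       percentile_persistence_rho = 0.99,
                       interval_drift_per_week = 0)
  coh <- generate_cohort(cfg)
  rho_s <- cor(coh$latent_percentile_scan, coh$latent_percentile_birth,
               method = "spearman")
  expect_gte(rho_s, 0.98)
})

test_that("any-APO rate is nondecreasing in the SGA risk ratio", {
  rates <- sapply(c(1, 2, 4), function(rr) {
    mean(sapply(1:3, function(s) {
      cfg <- cohort_config(n_records = 5000, seed = 100 + s,
                           apo_sga_risk_ratio = rr)
      coh <- generate_cohort(cfg)
      mean(Reduce(`|`, coh[c("apgar5_lt7", "instrumental_nrfs", "cesarean_nrfs",
                             "ph_lt_710", "stillbirth")]))
    }))
  })
  expect_true(all(diff(rates) >= 0))
})

test_that("latent scan percentile loses discrimination as interval drift grows", {
  aucs <- sapply(c(0, 0.1, 0.3), function(drift) {
    cfg <- cohort_config(n_records = 4000, seed = 17,
                         interval_drift_per_week = drift)
    coh <- generate_cohort(cfg)
    auc_delong(coh$latent_percentile_scan, coh$latent_percentile_birth < 10)$auc
  })
  expect_true(all(diff(aucs) < 0))
})

test_that("synthesised biometry reproduces the target EFW for each formula", {
  b4 <- synth_biometry(2495, 246, "hadlock4", seed = 3)
  expect_true(abs(efw("hadlock4", b4) - 2495) <= 12)  # within 0.5%
  bs <- synth_biometry(2421, 246, "stirnemann", seed = 3)
  expect_true(abs(efw("stirnemann", bs) - 2421) <= 12)
  ## reproducibility contract
  expect_identical(synth_biometry(2600, 250, "hadlock4", seed = 11),
                   synth_biometry(2600, 250, "hadlock4", seed = 11))
  ## an absurd target is infeasible within physiologic bounds
  expect_error(synth_biometry(10000, 246, "hadlock4", seed = 1), "not attainable")
})

test_that("tuned defaults give a hadlock4/stirnemann EFW offset like the calibration targets", {
  coh <- generate_cohort(cohort_config(n_records = 4000, seed = 21))
  m4 <- median(efw("hadlock4", coh))
  ms <- median(efw("stirnemann", coh))
  expect_equal(m4, 2495, tolerance = 0.02)
  expect_equal(ms / m4, 2421 / 2495, tolerance = 0.01)
})
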