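test_that("z-score engine: centering, normal-quantile and monotonicity properties", {
  std <- toy_zscore_standard(transform = "identity", cv = 0.11)
  med <- curve_median(246, std$parameters$median_curve)
  at_median <- epw_zscore(med, 246, std)
  expect_equal(at_median$percentile, 50)
  expect_equal(at_median$zscore, 0)
  ## efw = median * (1 + qnorm(0.9) * CV) must sit at the 90th percentile
  r <- epw_zscore(med * (1 + qnorm(0.9) * 0.11), 246, std)
  expect_equal(r$percentile, 90, tolerance = 0.1 / 90)
  ## strictly increasing in efw on a 100-weight grid (away from the clamp rails)
  grid <- seq(1500, 3800, length.out = 100)
  p <- epw_zscore(grid, 246, std)$percentile
  inner <- p > 0.01 & p < 99.99
  expect_true(all(diff(p[inner]) > 0))
  expect_error(epw_zscore(2500, 300, std), "envelope")
  expect_error(epw_zscore(-5, 246, std), "positive")
})

test_that("customized engine: reference neutrality and covariate effect signs", {
  std <- toy_customized_standard()
  ref <- reference_profile(std)
  ## reference mother: identical to a z-score standard centred on
  ## base_term_weight * proportionality(ga)
  equiv <- growth_standard("equiv", "zscore_curve", "hadlock4",
    parameters = list(
      median_curve = list(w_ref_g = std$parameters$base_term_weight_g,
                          ga_ref = 280, b1 = 0.0065, b2 = -5.32e-5),
      dispersion = list(transform = "identity", cv = 0.11)))
  for (w in c(2100, 2500, 2900)) {
    expect_equal(epw_customized(w, 246, ref, std)$percentile,
                 epw_zscore(w, 246, equiv)$percentile, tolerance = 1e-10)
  }
  ## taller mother -> larger expected weight -> lower percentile at fixed efw
  tall <- ref; tall$maternal_height <- 175
  expect_lt(epw_customized(2500, 246, tall, std)$percentile,
            epw_customized(2500, 246, ref, std)$percentile)
  ## doubling the expected weight strictly lowers the percentile
  boosted <- std
  boosted$parameters$scale <- 2
  expect_lt(epw_customized(2500, 246, ref, boosted)$percentile,
            epw_customized(2500, 246, ref, std)$percentile)
  ## missing covariate names the field
  incomplete <- ref; incomplete$parity <- NULL
  expect_error(epw_customized(2500, 246, incomplete, std), "parity")
})

test_that("quantile-grid engine: node identities and probit interpolation", {
  std <- toy_quantile_grid()
  p <- std$parameters
  for (k in seq_along(p$levels)) {
    got <- epw_quantile_grid(p$weights[2, k], p$ga_grid[2], std)$percentile
    expect_equal(got, p$levels[k], tolerance = 1e-9)
  }
  ## weight midway between the P25 and P50 nodes maps to the probit midpoint
  w_mid <- (p$weights[2, 3] + p$weights[2, 4]) / 2
  expected <- 100 * pnorm((qnorm(0.25) + qnorm(0.50)) / 2)
  expect_equal(epw_quantile_grid(w_mid, p$ga_grid[2], std)$percentile,
               expected, tolerance = 0.1 / expected)
  ## a non-monotone grid is rejected at load time
  bad <- p$weights
  bad[2, 3] <- bad[2, 4] + 1
  expect_error(growth_standard("bad_grid", "quantile_grid", "hadlock4",
                               parameters = list(ga_grid = p$ga_grid,
                                                 levels = p$levels,
                                                 weights = bad)),
               "strictly increasing in level")
})

test_that("weight_at_percentile inverts the percentile map", {
  stds <- list(toy_zscore_standard(), toy_quantile_grid())
  for (std in stds) {
    for (pc in c(5, 10, 25, 50, 75, 90, 95)) {
      w <- weight_at_percentile(pc, 246, std)
      back <- epw(std, w, 246)$percentile
      expect_lte(abs(back - pc), 0.1)
    }
  }
  ## centre identity for the z-score family
  zstd <- toy_zscore_standard()
  expect_equal(weight_at_percentile(50, 246, zstd),
               curve_median(246, zstd$parameters$median_curve))
  ## grid node identity
  g <- toy_quantile_grid()$parameters
  expect_equal(weight_at_percentile(95, g$ga_grid[3], toy_quantile_grid()),
               g$weights[3, 7], tolerance = 1e-9)
  ## customized inverse round trip at a non-reference profile
  cstd <- toy_customized_standard()
  prof <- data.frame(maternal_height = 170, parity = "1", sex = "male")
  for (pc in c(10, 50, 90)) {
    w <- weight_at_percentile(pc, 250, cstd, prof)
    expect_lte(abs(epw_customized(w, 250, prof, cstd)$percentile - pc), 0.1)
  }
  expect_error(weight_at_percentile(0, 246, zstd), "strictly in")
})

test_that("a quantile grid tabulated from a z-score standard reproduces its percentiles", {
  zstd <- toy_zscore_standard(sigma = 0.135)
  levels <- c(5, 10, 25, 50, 75, 90, 95)
  ga <- c(238, 245, 252, 259)
  weights <- sapply(levels, function(l) weight_at_percentile(l, ga, zstd)) |>
    matrix(nrow = length(ga))
  grid <- growth_standard("from_z", "quantile_grid", "hadlock4",
                          parameters = list(ga_grid = ga, levels = levels,
                                            weights = weights))
  for (ga_d in c(240, 246, 253)) {
    span <- weight_at_percentile(c(5, 95), ga_d, zstd)
    ws <- seq(span[1], span[2], length.out = 60)
    pz <- epw_zscore(ws, ga_d, zstd)$percentile
    pg <- epw_quantile_grid(ws, ga_d, grid)$percentile
    expect_lt(max(abs(pz - pg)), 0.5)
  }
})

test_that("per-standard dispatch computes six results and tracks exclusions", {
  coh <- generate_cohort(small_cohort_config(n = 60, seed = 9))
  stds <- bundled_standards()
  expect_named(stds, c("msuh_nc", "msuh_cust", "figueras", "intergrowth21",
                       "who", "fmf"))
  ep <- epw_all_standards(coh, stds)
  expect_equal(nrow(ep), 60 * 6)
  expect_true(all(!ep$excluded))
  expect_true(all(ep$percentile > 0 & ep$percentile < 100))

  ## missing paternal height excludes the record from msuh_cust only
  coh$paternal_height[5] <- NA
  ep2 <- epw_all_standards(coh, stds)
  gone <- ep2[ep2$record_id == "P00005", ]
  expect_equal(gone$excluded, gone$standard_id == "msuh_cust")
  expect_match(gone$reason[gone$standard_id == "msuh_cust"], "paternal_height")

  ## exclusion bookkeeping: analyzed + excluded = cohort size per standard
  tally <- attr(ep2, "exclusions")
  expect_true(all(tally$analyzed + tally$excluded == nrow(coh)))
})

test_that("percentile is strictly increasing in EFW for every bundled standard", {
  stds <- bundled_standards()
  prof <- data.frame(maternal_age = 33, maternal_bmi = 23, maternal_height = 163,
                     paternal_height = 176, parity = "0", sex = "female")
  grid <- seq(1600, 3600, length.out = 100)
  for (std in stds) {
    p <- epw(std, grid, 246, prof)$percentile
    inner <- p > 0.01 & p < 99.99  # clamping creates ties only at the rails
    expect_true(all(diff(p[inner]) > 0), label = std$standard_id)
  }
})

test_that("calibration reproduces the target EPW distribution summary", {
  cfg <- cohort_config(n_records = 6000, seed = 202)
  coh <- generate_cohort(cfg)
  targets <- c(12, 55, 93)
  for (id in c("msuh_nc", "msuh_cust", "who")) {
    cal <- calibrate_standard(bundled_standards()[[id]], coh, targets)
    ep <- epw_all_standards(coh, list(cal))
    q <- quantile(ep$percentile, c(0.1, 0.5, 0.9), names = FALSE)
    expect_equal(q[2], targets[2], tolerance = 0.02, label = id)
    ## spread calibrated through the outer quantile pair
    expect_equal(q[3] - q[1], targets[3] - targets[1], tolerance = 0.08,
                 label = id)
  }
})

test_that("chart export tabulates weights increasing in level and GA", {
  for (std in bundled_standards()[c("msuh_nc", "msuh_cust", "who")]) {
    ch <- standard_chart(std, ga_days = 238:258)
    expect_equal(names(ch), c("ga_days", "p5", "p10", "p25", "p50", "p75", "p90", "p95"))
    w <- as.matrix(ch[-1])
    expect_true(all(apply(w, 1, diff) > 0))   # increasing in level
    expect_true(all(apply(w, 2, diff) > 0))   # increasing in GA
  }
})

test_that("standard JSON files round-trip through write/load", {
  for (std in bundled_standards()[c("msuh_cust", "who")]) {
    path <- withr::local_tempfile(fileext = ".json")
    write_standard(std, path)
    back <- load_standard(path)
    coh <- generate_cohort(small_cohort_config(n = 25, seed = 55))
    a <- epw_all_standards(coh, list(std))
    b <- epw_all_standards(coh, list(back))
    expect_equal(b$percentile, a$percentile, tolerance = 1e-12)
  }
})
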