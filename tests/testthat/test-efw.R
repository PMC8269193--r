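test_that("Hadlock-4 matches a hand evaluation of the log10-linear model", {
  ## Independent evaluation of the published expression, measurements in cm.
  bpd <- 8.7; hc <- 31.5; ac <- 30.5; fl <- 6.8
  expected <- 10^(1.3596 + 0.0064 * hc + 0.0424 * ac + 0.174 * fl +
                    0.00061 * bpd * ac - 0.00386 * ac * fl)
  got <- efw("hadlock4", c(bpd_mm = 87, hc_mm = 315, ac_mm = 305, fl_mm = 68))
  expect_equal(got, expected, tolerance = 0.1 / expected)

  ## Stirnemann HC/AC model, measurements in metres.
  u_ac <- 0.305; u_hc <- 0.315
  expected_s <- exp(5.08482 - 54.06633 * u_ac^3 - 95.80076 * u_ac^3 * log(u_ac) +
                      3.13637 * u_hc)
  expect_equal(efw("stirnemann", c(hc_mm = 315, ac_mm = 305)), expected_s,
               tolerance = 1e-10)
})

test_that("a constant-only formula returns 10^c for any biometry", {
  f <- efw_formula("const_test", "log10_poly", "ac",
                   coefficients = list(list(coef = 3, vars = character())))
  expect_equal(efw(f, c(ac_mm = 210)), 1000)
  expect_equal(efw(f, c(ac_mm = 355)), 1000)
})

test_that("EFW is strictly increasing in each measurement over the physiologic envelope", {
  base <- list(bpd_mm = 87, hc_mm = 315, ac_mm = 308, fl_mm = 67)
  for (fid in c("hadlock4", "hadlock3", "stirnemann")) {
    f <- get_efw_formula(fid)
    for (m in f$required_measurements) {
      col <- paste0(m, "_mm")
      grid <- seq(base[[col]] * 0.75, base[[col]] * 1.25, length.out = 40)
      b <- base
      vals <- vapply(grid, function(v) {
        b[[col]] <- v
        efw(f, b)
      }, numeric(1))
      expect_true(all(diff(vals) > 0),
                  label = sprintf("%s increasing in %s", fid, m))
    }
  }
})

test_that("missing or nonpositive measurements raise informative errors", {
  expect_error(efw("hadlock4", c(hc_mm = 315, ac_mm = 308, fl_mm = 67)),
               "incomplete biometry.*bpd")
  expect_error(efw("stirnemann", c(hc_mm = 315, ac_mm = -1)), "positive")
})

test_that("formula registry enforces unique ids and supports lookup", {
  f <- efw_formula("dup_test", "log10_poly", "ac",
                   coefficients = list(list(coef = 3, vars = character())))
  register_formula(f)
  expect_error(register_formula(f), "already registered")
  expect_error(get_efw_formula("no_such_formula"), "no EFW formula")
  stir <- get_efw_formula("stirnemann")
  expect_setequal(stir$required_measurements, c("hc", "ac"))
  h3 <- get_efw_formula("hadlock3")
  expect_setequal(h3$required_measurements, c("hc", "ac", "fl"))
})

test_that("bundled formula files round-trip through the JSON loader", {
  path <- system.file("extdata", "formulas", "hadlock4.json", package = "epwscreen")
  f <- load_efw_formula(path)
  expect_s3_class(f, "efw_formula")
  b <- c(bpd_mm = 87, hc_mm = 315, ac_mm = 305, fl_mm = 68)
  expect_equal(efw(f, b), efw("hadlock4", b))
})
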