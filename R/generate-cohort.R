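.apo_components <- c("apgar5_lt7", "instrumental_nrfs", "cesarean_nrfs",
                     "ph_lt_710", "stillbirth")

.cohort_columns <- c("record_id", "maternal_age", "maternal_bmi",
                     "maternal_height", "paternal_height", "parity",
                     "ethnicity", "smoker", "sex",
                     "bpd_mm", "hc_mm", "ac_mm", "fl_mm",
                     "ga_scan_days", "ga_delivery_days", "birthweight_g",
                     .apo_components)

.latent_columns <- c("latent_percentile_scan", "latent_percentile_birth")

## Copula correlation between scan and birth latent percentiles at an
## ultrasound-delivery interval of d days.
persistence_rho <- function(cfg, interval_days) {
  cfg$percentile_persistence_rho *
    exp(-cfg$interval_drift_per_week * interval_days / 7)
}

## Sex-specific multiplicative factor on median weight.
sex_factor <- function(cfg, sex) {
  ifelse(sex == "male", exp(cfg$sex_effect_log), exp(-cfg$sex_effect_log))
}

#' Generate a synthetic pregnancy cohort
#'
#' Simulates one row per pregnancy: maternal covariates matched to the
#' configured marginals, scan and delivery gestational ages, fetal biometry
#' consistent with the Hadlock-4 EFW implied by the latent scan percentile,
#' birthweight derived from the latent birth percentile, and adverse
#' perinatal outcome flags with elevated risk when the latent birth
#' percentile is below 10.
#'
#' The latent percentiles follow a probit-scale Gaussian copula: the birth
#' z-score equals `rho(d)` times the scan z-score plus independent noise,
#' where `rho(d) = percentile_persistence_rho * exp(-interval_drift_per_week
#' * d / 7)` and `d` is the scan-delivery interval in days.  Covariates are
#' sampled independently of fetal size (only fetal sex shifts the weight
#' distribution), so customization covariates carry no true signal in the
#' simulated data.
#'
#' @param config a [cohort_config()] object.
#' @return a data.frame of class `pregnancy_cohort` with one row per
#'   pregnancy.  The two `latent_*` columns are simulation-internal ground
#'   truth; [write_cohort()] omits them unless asked.
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  n <- config$n_records
  if (n == 0) {
    return(empty_cohort())
  }
  with_preserved_seed(config$seed, generate_cohort_impl(config, n))
}

generate_cohort_impl <- function(cfg, n) {
  iqr_sd <- function(tgt) (tgt[3] - tgt[2]) / (2 * qnorm(0.75))

  maternal_age <- round(clamp(rnorm(n, cfg$maternal_age[1], iqr_sd(cfg$maternal_age)), 16, 52), 1)
  ## BMI is right-skewed: log-normal matched to the median and IQR spread.
  bmi_sdlog <- (log(cfg$maternal_bmi[3]) - log(cfg$maternal_bmi[2])) / (2 * qnorm(0.75))
  maternal_bmi <- round(clamp(exp(rnorm(n, log(cfg$maternal_bmi[1]), bmi_sdlog)), 14, 55), 1)
  maternal_height <- round(clamp(rnorm(n, cfg$maternal_height[1], iqr_sd(cfg$maternal_height)), 140, 195))
  paternal_height <- round(clamp(rnorm(n, cfg$paternal_height[1], iqr_sd(cfg$paternal_height)), 150, 210))

  parity <- sample(names(cfg$parity_probs), n, replace = TRUE, prob = cfg$parity_probs)
  ethnicity <- sample(names(cfg$ethnicity_probs), n, replace = TRUE, prob = cfg$ethnicity_probs)
  smoker <- runif(n) < cfg$smoking_prob
  sex <- ifelse(runif(n) < cfg$male_prob, "male", "female")

  ga_scan <- as.integer(clamp(round(rnorm(n, cfg$scan_ga_median, cfg$scan_ga_sd)),
                              cfg$scan_ga_range[1], cfg$scan_ga_range[2]))
  ga_delivery <- as.integer(clamp(round(rnorm(n, cfg$delivery_ga_median, cfg$delivery_ga_sd)),
                                  cfg$delivery_ga_range[1], cfg$delivery_ga_range[2]))

  ## Latent percentile copula.
  z_scan <- rnorm(n)
  rho_d <- persistence_rho(cfg, ga_delivery - ga_scan)
  z_birth <- rho_d * z_scan + sqrt(1 - rho_d^2) * rnorm(n)

  sf <- sex_factor(cfg, sex)
  true_scan_wt <- curve_median(ga_scan, cfg$growth_curve) * sf *
    exp(cfg$fetal_weight_sd_log * z_scan)
  efw_target <- true_scan_wt * exp(rnorm(n, 0, cfg$efw_noise_sd_log))

  jitter <- matrix(rnorm(n * 4, 0, cfg$biometry_jitter_sd_log), nrow = n)
  biom <- synth_biometry_impl(efw_target, ga_scan, get_efw_formula("hadlock4"), jitter)
  biom[] <- lapply(biom, function(x) round(x, 1))

  birthweight <- as.integer(round(curve_median(ga_delivery, cfg$growth_curve) * sf *
                                    exp(cfg$birthweight_sd_log * z_birth)))

  ## APO flags: per-component base rate, inflated by the configured relative
  ## risk when the latent birth percentile is below 10.
  rr <- rep_len(cfg$apo_sga_risk_ratio, length(cfg$apo_base_rates))
  small <- pnorm(z_birth) < 0.10
  apo <- matrix(FALSE, n, length(cfg$apo_base_rates),
                dimnames = list(NULL, names(cfg$apo_base_rates)))
  for (j in seq_along(cfg$apo_base_rates)) {
    p <- clamp(cfg$apo_base_rates[j] * ifelse(small, rr[j], 1), 0, 1)
    apo[, j] <- runif(n) < p
  }

  out <- data.frame(
    record_id = sprintf("P%05d", seq_len(n)),
    maternal_age = maternal_age,
    maternal_bmi = maternal_bmi,
    maternal_height = maternal_height,
    paternal_height = paternal_height,
    parity = parity,
    ethnicity = ethnicity,
    smoker = smoker,
    sex = sex,
    bpd_mm = biom$bpd_mm, hc_mm = biom$hc_mm,
    ac_mm = biom$ac_mm, fl_mm = biom$fl_mm,
    ga_scan_days = ga_scan,
    ga_delivery_days = ga_delivery,
    birthweight_g = birthweight,
    stringsAsFactors = FALSE
  )
  out[.apo_components] <- as.data.frame(apo)
  out$latent_percentile_scan <- 100 * pnorm(z_scan)
  out$latent_percentile_birth <- 100 * pnorm(z_birth)
  attr(out, "cohort_config") <- cfg
  class(out) <- c("pregnancy_cohort", "data.frame")
  out
}

empty_cohort <- function() {
  out <- data.frame(
    record_id = character(), maternal_age = numeric(), maternal_bmi = numeric(),
    maternal_height = numeric(), paternal_height = numeric(),
    parity = character(), ethnicity = character(), smoker = logical(),
    sex = character(), bpd_mm = numeric(), hc_mm = numeric(),
    ac_mm = numeric(), fl_mm = numeric(), ga_scan_days = integer(),
    ga_delivery_days = integer(), birthweight_g = integer(),
    stringsAsFactors = FALSE
  )
  for (f in .apo_components) out[[f]] <- logical()
  out$latent_percentile_scan <- numeric()
  out$latent_percentile_birth <- numeric()
  class(out) <- c("pregnancy_cohort", "data.frame")
  out
}
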