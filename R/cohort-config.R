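#' Configuration of the synthetic perinatal cohort generator
#'
#' Returns a validated configuration object holding every distributional
#' target, effect size and noise parameter of the generator, plus the seed.
#' The defaults describe a term singleton-pregnancy cohort with a routine
#' 34+0 to 36+6 week growth scan: maternal covariate marginals (medians and
#' interquartile ranges), a scan-percentile to birth-percentile Gaussian
#' copula whose correlation decays with the ultrasound-delivery interval,
#' an SGA rate of 9.4%, and adverse perinatal outcome (APO) rates of
#' 0.2-2.8% per component with elevated risk in SGA fetuses.
#'
#' @param n_records number of pregnancies to simulate.
#' @param seed integer RNG seed; generation is bit-reproducible given it.
#' @param maternal_age,maternal_bmi,maternal_height,paternal_height numeric
#'   `c(median, iqr_lo, iqr_hi)` marginal targets (years, kg/m2, cm, cm).
#' @param parity_probs probabilities over parity categories `0`, `1`, `2+`.
#' @param ethnicity_probs probabilities over `caucasian`, `asian`,
#'   `african`.
#' @param smoking_prob proportion of smokers.
#' @param male_prob proportion of male fetuses.
#' @param scan_ga_range,scan_ga_median,scan_ga_sd scan gestational age
#'   window (days, 34+0-36+6), centre and spread of the rounded-normal
#'   draw.
#' @param delivery_ga_range,delivery_ga_median,delivery_ga_sd same for
#'   delivery (37+0-42+0 weeks).
#' @param target_sga_rate population SGA proportion the birthweight
#'   reference cut realises.
#' @param percentile_persistence_rho copula correlation between the latent
#'   scan and birth percentiles at zero interval; in (0, 1).
#' @param interval_drift_per_week exponential decay rate of that
#'   correlation per week of scan-delivery interval (>= 0).
#' @param apo_base_rates named per-component APO probabilities for
#'   non-SGA fetuses (`apgar5_lt7`, `instrumental_nrfs`, `cesarean_nrfs`,
#'   `ph_lt_710`, `stillbirth`).
#' @param apo_sga_risk_ratio relative risk of each APO component given a
#'   latent birth percentile below 10; scalar or one value per component.
#' @param growth_curve log-quadratic ground-truth median weight curve
#'   (see [curve_median()]); defaults to 3310 g at 280 days.
#' @param fetal_weight_sd_log log-scale SD of true fetal weight around the
#'   median at the scan.
#' @param birthweight_sd_log log-scale SD of birthweight at fixed
#'   gestational age and sex.
#' @param sex_effect_log half the log-scale male-female median weight gap
#'   (males `+`, females `-`).
#' @param efw_noise_sd_log log-scale SD of ultrasound EFW measurement error
#'   around the true fetal weight.
#' @param biometry_jitter_sd_log log-scale SD of the per-measurement jitter
#'   applied to the biometry proportions before rescaling (this is what
#'   makes the Hadlock-3 and Stirnemann EFW differ stochastically from the
#'   Hadlock-4 EFW, as in real scans).
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_records = 9585,
                          seed = 1L,
                          maternal_age = c(median = 33.3, iqr_lo = 30.1, iqr_hi = 36.1),
                          maternal_bmi = c(median = 23.2, iqr_lo = 21.1, iqr_hi = 26.2),
                          maternal_height = c(median = 163, iqr_lo = 159, iqr_hi = 168),
                          paternal_height = c(median = 176, iqr_lo = 172, iqr_hi = 181),
                          parity_probs = c(`0` = 0.530, `1` = 0.389, `2+` = 0.081),
                          ethnicity_probs = c(caucasian = 0.9643, asian = 0.0115, african = 0.0242),
                          smoking_prob = 0.161,
                          male_prob = 0.515,
                          scan_ga_range = c(238L, 258L),
                          scan_ga_median = 246,
                          scan_ga_sd = 1.9,
                          delivery_ga_range = c(259L, 294L),
                          delivery_ga_median = 280,
                          delivery_ga_sd = 8.2,
                          target_sga_rate = 0.094,
                          percentile_persistence_rho = 0.97,
                          interval_drift_per_week = 0.08,
                          apo_base_rates = c(apgar5_lt7 = 0.00345,
                                             instrumental_nrfs = 0.01486,
                                             cesarean_nrfs = 0.02234,
                                             ph_lt_710 = 0.02407,
                                             stillbirth = 0.00161),
                          apo_sga_risk_ratio = c(apgar5_lt7 = 3.86,
                                                 instrumental_nrfs = 2.39,
                                                 cesarean_nrfs = 3.52,
                                                 ph_lt_710 = 2.07,
                                                 stillbirth = 3.44),
                          growth_curve = list(w_ref_g = 3310, ga_ref = 280,
                                              b1 = 0.0065, b2 = -5.32e-5),
                          fetal_weight_sd_log = 0.11,
                          birthweight_sd_log = 0.11,
                          sex_effect_log = 0.022,
                          efw_noise_sd_log = 0.02,
                          biometry_jitter_sd_log = 0.012) {
  cfg <- structure(
    list(n_records = n_records, seed = seed,
         maternal_age = maternal_age, maternal_bmi = maternal_bmi,
         maternal_height = maternal_height, paternal_height = paternal_height,
         parity_probs = parity_probs, ethnicity_probs = ethnicity_probs,
         smoking_prob = smoking_prob, male_prob = male_prob,
         scan_ga_range = as.integer(scan_ga_range),
         scan_ga_median = scan_ga_median, scan_ga_sd = scan_ga_sd,
         delivery_ga_range = as.integer(delivery_ga_range),
         delivery_ga_median = delivery_ga_median, delivery_ga_sd = delivery_ga_sd,
         target_sga_rate = target_sga_rate,
         percentile_persistence_rho = percentile_persistence_rho,
         interval_drift_per_week = interval_drift_per_week,
         apo_base_rates = apo_base_rates,
         apo_sga_risk_ratio = apo_sga_risk_ratio,
         growth_curve = growth_curve,
         fetal_weight_sd_log = fetal_weight_sd_log,
         birthweight_sd_log = birthweight_sd_log,
         sex_effect_log = sex_effect_log,
         efw_noise_sd_log = efw_noise_sd_log,
         biometry_jitter_sd_log = biometry_jitter_sd_log),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' Validate a cohort configuration
#'
#' Checks the invariants of [cohort_config()] and fails with an error
#' naming the offending field.
#'
#' @param cfg a `cohort_config` object (or bare list with the same fields).
#' @return the validated config, invisibly classed.
#' @export
validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_records)) config_error("n_records", "must be a single non-negative integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  for (f in c("maternal_age", "maternal_bmi", "maternal_height", "paternal_height")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 3 || any(is.na(v))) {
      config_error(f, "must be c(median, iqr_lo, iqr_hi)")
    }
    if (!(v[2] < v[1] && v[1] < v[3])) config_error(f, "needs iqr_lo < median < iqr_hi")
  }
  for (f in c("parity_probs", "ethnicity_probs")) {
    v <- cfg[[f]]
    if (!is_prob(v)) config_error(f, "must be probabilities in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9) config_error(f, "must sum to 1")
  }
  for (f in c("smoking_prob", "male_prob", "target_sga_rate")) {
    if (!is_prob(cfg[[f]]) || length(cfg[[f]]) != 1) config_error(f, "must be a proportion in [0, 1]")
  }
  for (f in c("scan_ga_range", "delivery_ga_range")) {
    v <- cfg[[f]]
    if (length(v) != 2 || v[1] > v[2]) config_error(f, "must be a nonempty [lo, hi] day range")
  }
  if (cfg$delivery_ga_range[1] <= cfg$scan_ga_range[2]) {
    config_error("delivery_ga_range", "must start after the scan window ends")
  }
  rho <- cfg$percentile_persistence_rho
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho <= 0 || rho >= 1) {
    config_error("percentile_persistence_rho", "must lie strictly in (0, 1)")
  }
  if (!is.numeric(cfg$interval_drift_per_week) || cfg$interval_drift_per_week < 0) {
    config_error("interval_drift_per_week", "must be >= 0")
  }
  if (!is_prob(cfg$apo_base_rates) || is.null(names(cfg$apo_base_rates))) {
    config_error("apo_base_rates", "must be named probabilities in [0, 1]")
  }
  rr <- cfg$apo_sga_risk_ratio
  if (!is.numeric(rr) || any(is.na(rr)) || any(rr < 0) ||
      !(length(rr) %in% c(1, length(cfg$apo_base_rates)))) {
    config_error("apo_sga_risk_ratio", "must be a non-negative scalar or one value per APO component")
  }
  for (f in c("fetal_weight_sd_log", "birthweight_sd_log", "efw_noise_sd_log",
              "biometry_jitter_sd_log")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) config_error(f, "must be >= 0")
  }
  invisible(structure(cfg, class = "cohort_config"))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: n = %d, seed = %s\n",
              x$n_records, format(x$seed)))
  cat(sprintf("  scan window %d-%d d, delivery %d-%d d, target SGA rate %.1f%%\n",
              x$scan_ga_range[1], x$scan_ga_range[2],
              x$delivery_ga_range[1], x$delivery_ga_range[2],
              100 * x$target_sga_rate))
  cat(sprintf("  percentile persistence rho = %.3f, drift = %.3f / week\n",
              x$percentile_persistence_rho, x$interval_drift_per_week))
  invisible(x)
}
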