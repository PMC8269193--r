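## Cross-standard comparisons: APO detection by EPW < 10, pairwise
## AUC / sensitivity / APO-proportion tests, and the ultrasound-delivery
## interval subanalysis.

## Wide matrix of percentiles: rows = records, columns = standards.
epw_wide <- function(epw_table) {
  stds <- unique(epw_table$standard_id)
  ids <- unique(epw_table$record_id)
  m <- matrix(NA_real_, length(ids), length(stds),
              dimnames = list(ids, stds))
  idx <- cbind(match(epw_table$record_id, ids),
               match(epw_table$standard_id, stds))
  vals <- ifelse(epw_table$excluded, NA_real_, epw_table$percentile)
  m[idx] <- vals
  m
}

#' APO detection by EPW below the 10th percentile
#'
#' For every standard, counts and percentages of each adverse perinatal
#' outcome (the five components and the any-APO composite) occurring in
#' records that screened positive (EPW strictly below `cutoff`).  An
#' SGA-at-birth row shows the same detection by the gold standard itself.
#' Percentages use the total cohort count of each outcome as denominator.
#'
#' @param epw_table long EPW table from [epw_all_standards()].
#' @param outcomes outcome flags from [derive_outcomes()].
#' @param cutoff screen-positive EPW threshold (default 10).
#' @return list with `totals` (named outcome counts), `detection` (long
#'   data.frame: classifier, outcome, detected, total, pct) and
#'   `pairwise_any_apo` (symmetric p-value matrix of two-proportion tests
#'   on any-APO detection between standards).
#' @export
apo_detection_by_epw10 <- function(epw_table, outcomes, cutoff = 10) {
  comp <- c(.apo_components, "any_apo")
  totals <- vapply(comp, function(f) sum(outcomes[[f]]), integer(1))
  wide <- epw_wide(epw_table)
  outcomes <- outcomes[match(rownames(wide), outcomes$record_id), ]
  classifiers <- c("sga_birth", colnames(wide))
  rows <- list()
  detected <- matrix(NA_integer_, length(classifiers), length(comp),
                     dimnames = list(classifiers, comp))
  for (cl in classifiers) {
    pos <- if (cl == "sga_birth") outcomes$sga else
      !is.na(wide[, cl]) & wide[, cl] < cutoff
    for (f in comp) {
      k <- sum(pos & outcomes[[f]])
      detected[cl, f] <- k
      rows[[length(rows) + 1]] <- data.frame(
        classifier = cl, outcome = f, detected = k, total = totals[[f]],
        pct = if (totals[[f]] > 0) 100 * k / totals[[f]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  stds <- colnames(wide)
  pw <- matrix(NA_real_, length(stds), length(stds), dimnames = list(stds, stds))
  diag(pw) <- 1
  for (i in seq_along(stds)) {
    for (j in seq_along(stds)) {
      if (i < j) {
        p <- two_proportion_test(detected[stds[i], "any_apo"], totals[["any_apo"]],
                                 detected[stds[j], "any_apo"], totals[["any_apo"]])$p_value
        pw[i, j] <- pw[j, i] <- p
      }
    }
  }
  list(totals = totals,
       detection = do.call(rbind, rows),
       pairwise_any_apo = pw)
}

#' Pairwise standard comparisons: AUC and sensitivity at 90% specificity
#'
#' For every pair of standards, the DeLong paired AUC test on their shared
#' records, and a two-proportion test comparing the numbers of cases each
#' standard detects at its own 10%-FPR threshold.
#'
#' @param epw_table long EPW table from [epw_all_standards()].
#' @param outcomes outcome flags from [derive_outcomes()]; `sga` is the
#'   outcome compared.
#' @param fpr the shared specificity constraint, percent (default 10, i.e.
#'   90% specificity).
#' @return list of symmetric matrices `auc_p` (diagonal 1) and `sens_p`.
#' @export
pairwise_standard_tests <- function(epw_table, outcomes, fpr = 10) {
  wide <- epw_wide(epw_table)
  outcomes <- outcomes[match(rownames(wide), outcomes$record_id), ]
  stds <- colnames(wide)
  auc_p <- matrix(NA_real_, length(stds), length(stds), dimnames = list(stds, stds))
  sens_p <- auc_p
  diag(auc_p) <- 1
  diag(sens_p) <- 1
  for (i in seq_along(stds)) {
    for (j in seq_along(stds)) {
      if (i >= j) next
      ok <- !is.na(wide[, i]) & !is.na(wide[, j])
      lab <- outcomes$sga[ok]
      auc_p[i, j] <- auc_p[j, i] <-
        delong_paired_test(wide[ok, i], wide[ok, j], lab)$p_value
      si <- sensitivity_at_fpr(wide[ok, i], lab, fpr)
      sj <- sensitivity_at_fpr(wide[ok, j], lab, fpr)
      ki <- round(si$sensitivity / 100 * si$n_pos)
      kj <- round(sj$sensitivity / 100 * sj$n_pos)
      sens_p[i, j] <- sens_p[j, i] <-
        two_proportion_test(ki, si$n_pos, kj, sj$n_pos)$p_value
    }
  }
  list(auc_p = auc_p, sens_p = sens_p)
}

#' Week bucket of an ultrasound-delivery interval
#'
#' Buckets 1-6 cover closed day ranges 8-14, 15-21, ..., 43-49; intervals
#' outside 8-49 days (including 1-7 days, which have no bucket) return
#' `NA` and are excluded from the stratified analysis.
#'
#' @param interval_days integer days between scan and delivery.
#' @return integer bucket index 1-6 or `NA`.
#' @export
interval_stratum <- function(interval_days) {
  b <- (as.integer(interval_days) - 1L) %/% 7L
  b[interval_days < 8 | interval_days > 49] <- NA_integer_
  b
}

#' Screening evaluation stratified by ultrasound-delivery interval
#'
#' Bins records into the six week-buckets of [interval_stratum()] and runs
#' the full screening evaluation (AUC, sensitivities at the target FPRs,
#' logistic OR per percentile point) per stratum and standard.  Strata in
#' which a standard sees only one outcome class are reported as not
#' evaluable rather than erroring the run.
#'
#' @param records cohort data.frame.
#' @param epw_table long EPW table from [epw_all_standards()].
#' @param outcomes outcome flags from [derive_outcomes()].
#' @param fprs target FPRs in percent.
#' @return data.frame with one row per stratum and standard: `stratum`,
#'   `day_lo`, `day_hi`, `n`, `n_pos`, `evaluable`, `auc`, `auc_ci_low`,
#'   `auc_ci_high`, one `sens_fpr<t>` column per target, `or`, `or_ci_low`,
#'   `or_ci_high`.
#' @export
stratify_by_interval <- function(records, epw_table, outcomes,
                                 fprs = c(5, 10, 15, 20)) {
  interval <- records$ga_delivery_days - records$ga_scan_days
  stratum <- interval_stratum(interval)
  wide <- epw_wide(epw_table)
  wide <- wide[match(records$record_id, rownames(wide)), , drop = FALSE]
  outcomes <- outcomes[match(records$record_id, outcomes$record_id), ]
  out <- list()
  for (b in 1:6) {
    in_b <- !is.na(stratum) & stratum == b
    for (std in colnames(wide)) {
      sc <- wide[in_b, std]
      lab <- outcomes$sga[in_b]
      ok <- !is.na(sc)
      row <- data.frame(stratum = b, day_lo = 7 * b + 1, day_hi = 7 * b + 7,
                        standard_id = std, n = sum(ok),
                        n_pos = sum(lab[ok]), evaluable = FALSE,
                        auc = NA_real_, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                        stringsAsFactors = FALSE)
      for (f in fprs) row[[paste0("sens_fpr", f)]] <- NA_real_
      row$or <- NA_real_
      row$or_ci_low <- NA_real_
      row$or_ci_high <- NA_real_
      if (sum(lab[ok]) > 0 && sum(!lab[ok]) > 0) {
        row$evaluable <- TRUE
        ev <- screen_eval(sc[ok], lab[ok], fprs)
        row$auc <- ev$auc$auc
        row$auc_ci_low <- ev$auc$ci_low
        row$auc_ci_high <- ev$auc$ci_high
        for (f in fprs) {
          row[[paste0("sens_fpr", f)]] <-
            ev$by_fpr$sensitivity[ev$by_fpr$target_fpr == f]
        }
        ## small strata can sit near separation; the fit either converges
        ## (possibly with saturated fitted probabilities) or is reported NA
        lr <- tryCatch(suppressWarnings(logistic_or_per_percent(sc[ok], lab[ok])),
                       error = function(e) NULL)
        if (!is.null(lr)) {
          row$or <- lr$or
          row$or_ci_low <- lr$ci_low
          row$or_ci_high <- lr$ci_high
        }
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  attr(res, "n_in_range") <- sum(!is.na(stratum))
  res
}
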