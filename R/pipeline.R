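## End-to-end orchestration: simulate (or read) a cohort, compute EPW under
## every standard, derive outcomes, evaluate, and write table artifacts.

#' Configuration of a full pipeline run
#'
#' @param output_dir directory for all artifacts (created if absent).
#' @param cohort either a [cohort_config()] (simulate) or a path to a
#'   cohort CSV (read).
#' @param standards named list of `growth_standard`s, or a directory of
#'   standard JSON files.
#' @param reference a `bw_reference`, a reference CSV path, or `NULL` to
#'   derive the reference from the generator configuration.
#' @param fprs target false-positive rates, percent; unique, in (0, 100).
#' @param interval_analysis run the ultrasound-delivery interval
#'   subanalysis.
#' @param seed run seed; each stage derives a named substream from it so
#'   partial re-runs stay reproducible.
#' @return list of class `run_config`.
#' @export
run_config <- function(output_dir,
                       cohort = cohort_config(),
                       standards = bundled_standards(),
                       reference = NULL,
                       fprs = c(5, 10, 15, 20),
                       interval_analysis = TRUE,
                       seed = 1L) {
  if (is.character(standards)) standards <- bundled_standards(standards)
  if (length(standards) == 0) config_error("standards", "at least one growth standard is required")
  if (anyDuplicated(fprs) || any(fprs <= 0 | fprs >= 100)) {
    config_error("fprs", "must be unique values strictly inside (0, 100)")
  }
  if (is.character(cohort) && !file.exists(cohort)) {
    config_error("cohort", paste("file not found:", cohort))
  }
  structure(list(output_dir = output_dir, cohort = cohort,
                 standards = standards, reference = reference,
                 fprs = sort(fprs), interval_analysis = interval_analysis,
                 seed = as.integer(seed)),
            class = "run_config")
}

## Named substream seeds, kept well below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + match(stage, c("simulate", "epw", "evaluate"))) %% 2000000011L
}

#' Run the full screening pipeline
#'
#' Stages: cohort (simulate or read), birthweight reference, per-standard
#' EPW, outcome flags, screening evaluation per standard, pairwise tests,
#' APO detection, and optionally the interval subanalysis.  All numeric
#' artifacts are written under `output_dir`; re-running the same
#' configuration reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all in-memory results plus `manifest`,
#'   the written-artifact manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$output_dir, f)

  ## -- cohort ----------------------------------------------------------------
  if (is.character(config$cohort)) {
    cohort <- read_cohort(config$cohort)
    gen_cfg <- NULL
  } else {
    gen_cfg <- config$cohort
    gen_cfg$seed <- stage_seed(config$seed, "simulate")
    cohort <- generate_cohort(gen_cfg)
  }
  write_cohort(cohort, out_path("cohort.csv"))

  ## -- reference -------------------------------------------------------------
  reference <- config$reference
  if (is.null(reference)) {
    if (is.null(gen_cfg)) {
      stop("stage 'reference': a birthweight reference is required when the cohort is read from file")
    }
    reference <- reference_from_config(gen_cfg)
  } else if (is.character(reference)) {
    reference <- read_reference(reference)
  }
  write_reference(reference, out_path("reference.csv"))

  ## -- EPW + outcomes ----------------------------------------------------------
  epw_table <- epw_all_standards(cohort, config$standards)
  write.csv(epw_table, out_path("epw.csv"), row.names = FALSE, quote = FALSE)
  outcomes <- derive_outcomes(cohort, reference)

  ## -- evaluation --------------------------------------------------------------
  wide <- epw_wide(epw_table)
  ord <- match(rownames(wide), outcomes$record_id)
  evals <- lapply(colnames(wide), function(std) {
    ok <- !is.na(wide[, std])
    screen_eval(wide[ok, std], outcomes$sga[ord][ok], config$fprs)
  })
  names(evals) <- colnames(wide)
  pairwise <- pairwise_standard_tests(epw_table, outcomes)
  apo <- apo_detection_by_epw10(epw_table, outcomes)
  ors <- lapply(colnames(wide), function(std) {
    ok <- !is.na(wide[, std])
    tryCatch(suppressWarnings(logistic_or_per_percent(wide[ok, std], outcomes$sga[ord][ok])),
             error = function(e) NULL)
  })
  names(ors) <- colnames(wide)
  strata <- if (config$interval_analysis) {
    stratify_by_interval(cohort, epw_table, outcomes, config$fprs)
  }

  ## -- artifacts ---------------------------------------------------------------
  results <- list(
    n_records = nrow(cohort),
    sga_rate = mean(outcomes$sga),
    screen_eval = lapply(evals, function(e) {
      list(auc = e$auc, by_fpr = e$by_fpr)
    }),
    logistic_or = ors,
    pairwise = pairwise,
    apo_detection = apo,
    interval_strata = strata
  )
  jsonlite::write_json(results, out_path("results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, dataframe = "rows", matrix = "rowmajor")

  write.csv(render_table1(cohort, epw_table, outcomes), out_path("table1.csv"),
            row.names = FALSE)
  write.csv(render_apo_table(apo), out_path("table2.csv"), row.names = FALSE)
  write.csv(render_screen_table(evals), out_path("table3.csv"), row.names = FALSE)
  write.csv(render_pairwise_table(pairwise, apo), out_path("table4.csv"),
            row.names = FALSE)
  if (!is.null(strata)) {
    write.csv(render_interval_table(strata), out_path("table5.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    n_records = nrow(cohort),
    standards = lapply(config$standards, function(s)
      list(standard_id = s$standard_id, family = s$family,
           efw_formula_id = s$efw_formula_id, version = s$version)),
    exclusions = attr(epw_table, "exclusions"),
    artifacts = local({
      fs <- list.files(config$output_dir, pattern = "\\.(csv|json)$")
      fs <- setdiff(fs, "manifest.json")
      as.list(setNames(unname(tools::md5sum(file.path(config$output_dir, fs))), fs))
    })
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  invisible(list(cohort = cohort, reference = reference, epw = epw_table,
                 outcomes = outcomes, evals = evals, pairwise = pairwise,
                 apo = apo, logistic_or = ors, strata = strata,
                 manifest = manifest))
}

## ---- table renderers -------------------------------------------------------

q3 <- function(x) quantile(x, c(0.5, 0.25, 0.75), names = FALSE, na.rm = TRUE)
fmt_med_iqr <- function(x, digits = 1) {
  q <- q3(x)
  sprintf("%.*f (%.*f-%.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Cohort descriptive table (baseline, ultrasound, perinatal)
#'
#' @param cohort cohort data.frame.
#' @param epw_table long EPW table.
#' @param outcomes outcome flags.
#' @return two-column data.frame (characteristic, value).
#' @export
render_table1 <- function(cohort, epw_table, outcomes) {
  n <- nrow(cohort)
  row <- function(characteristic, value) data.frame(characteristic, value,
                                                    stringsAsFactors = FALSE)
  rows <- list(
    row("pregnancies_n", as.character(n)),
    row("maternal_age_years", fmt_med_iqr(cohort$maternal_age)),
    row("maternal_bmi", fmt_med_iqr(cohort$maternal_bmi)),
    row("maternal_height_cm", fmt_med_iqr(cohort$maternal_height, 0)),
    row("paternal_height_cm", fmt_med_iqr(cohort$paternal_height, 0)),
    row("parity_0", count_pct_label(sum(cohort$parity == "0"), n)),
    row("parity_1", count_pct_label(sum(cohort$parity == "1"), n)),
    row("parity_2plus", count_pct_label(sum(cohort$parity == "2+"), n)),
    row("smoking", count_pct_label(sum(cohort$smoker), n)),
    row("ga_scan_weeks", fmt_med_iqr(cohort$ga_scan_days / 7)),
    row("ga_delivery_weeks", fmt_med_iqr(cohort$ga_delivery_days / 7))
  )
  for (fid in c("hadlock4", "stirnemann")) {
    f <- get_efw_formula(fid)
    ok <- rep(TRUE, n)
    for (m in f$required_measurements) ok <- ok & !is.na(cohort[[paste0(m, "_mm")]])
    rows[[length(rows) + 1]] <-
      row(paste0("efw_g_", fid), fmt_med_iqr(efw(f, cohort[ok, , drop = FALSE]), 0))
  }
  fmt_p50_1090 <- function(x) {
    q <- quantile(x, c(0.5, 0.1, 0.9), names = FALSE, na.rm = TRUE)
    sprintf("%.1f (%.1f-%.1f)", q[1], q[2], q[3])
  }
  for (std in unique(epw_table$standard_id)) {
    p <- epw_table$percentile[epw_table$standard_id == std & !epw_table$excluded]
    rows[[length(rows) + 1]] <- row(paste0("percentile_", std), fmt_p50_1090(p))
  }
  rows[[length(rows) + 1]] <- row("birthweight_g", fmt_med_iqr(cohort$birthweight_g, 0))
  rows[[length(rows) + 1]] <- row("sga_birth", count_pct_label(sum(outcomes$sga), n))
  for (f in c(.apo_components, "any_apo")) {
    rows[[length(rows) + 1]] <- row(f, count_pct_label(sum(outcomes[[f]]), n))
  }
  do.call(rbind, rows)
}

#' APO detection table ("k (pct%)" cells per classifier and outcome)
#' @param apo result of [apo_detection_by_epw10()].
#' @return wide data.frame, one row per classifier.
#' @export
render_apo_table <- function(apo) {
  det <- apo$detection
  classifiers <- unique(det$classifier)
  comp <- unique(det$outcome)
  out <- data.frame(classifier = classifiers, stringsAsFactors = FALSE)
  for (f in comp) {
    out[[f]] <- vapply(classifiers, function(cl) {
      r <- det[det$classifier == cl & det$outcome == f, ]
      count_pct_label(r$detected, r$total)
    }, character(1))
  }
  rbind(data.frame(classifier = "total_cohort",
                   as.list(setNames(as.character(apo$totals), comp)),
                   stringsAsFactors = FALSE),
        out)
}

#' AUC / sensitivity / threshold table, one row per standard
#' @param evals named list of [screen_eval()] results.
#' @return data.frame.
#' @export
render_screen_table <- function(evals) {
  do.call(rbind, lapply(names(evals), function(std) {
    e <- evals[[std]]
    out <- data.frame(standard_id = std,
                      auc = sprintf("%.2f (%.2f-%.2f)", e$auc$auc,
                                    e$auc$ci_low, e$auc$ci_high),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(e$by_fpr))) {
      r <- e$by_fpr[i, ]
      out[[sprintf("fpr%g", r$target_fpr)]] <-
        sprintf("%.1f (%.1f-%.1f) (Thr: %.1f)", round_half_up(r$sensitivity),
                round_half_up(r$ci_low), round_half_up(r$ci_high),
                round_half_up(r$threshold_percentile))
    }
    out
  }))
}

#' Pairwise p-value table (AUC, sensitivity, APO detection)
#' @param pairwise result of [pairwise_standard_tests()].
#' @param apo result of [apo_detection_by_epw10()].
#' @return long data.frame of standard pairs and p-values.
#' @export
render_pairwise_table <- function(pairwise, apo) {
  stds <- rownames(pairwise$auc_p)
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  rows <- list()
  for (i in seq_along(stds)) {
    for (j in seq_along(stds)) {
      if (i >= j) next
      rows[[length(rows) + 1]] <- data.frame(
        standard_a = stds[i], standard_b = stds[j],
        auc_p = fmt_p(pairwise$auc_p[i, j]),
        sens_p = fmt_p(pairwise$sens_p[i, j]),
        apo_p = fmt_p(apo$pairwise_any_apo[stds[i], stds[j]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Interval-stratified AUC / sensitivity table
#' @param strata result of [stratify_by_interval()].
#' @return data.frame.
#' @export
render_interval_table <- function(strata) {
  out <- strata
  out$interval <- sprintf("%d week%s (%d-%d days)", out$stratum,
                          ifelse(out$stratum > 1, "s", ""), out$day_lo, out$day_hi)
  num <- vapply(out, is.numeric, logical(1)) & names(out) %in%
    c("auc", "auc_ci_low", "auc_ci_high", grep("^sens_fpr", names(out), value = TRUE),
      "or", "or_ci_low", "or_ci_high")
  out[num] <- lapply(out[num], function(x) round(x, 4))
  out[c("interval", setdiff(names(strata), c("stratum", "day_lo", "day_hi")))]
}
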