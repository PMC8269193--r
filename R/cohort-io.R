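## Cohort CSV round trip and record validation.

#' Write a pregnancy cohort to CSV
#'
#' Writes one row per pregnancy with all analysis-visible fields.  The
#' latent simulation percentiles are excluded unless `include_latent = TRUE`
#' (debugging only); they are never analysis inputs.
#'
#' @param records a cohort data.frame, e.g. from [generate_cohort()].
#' @param path output file path.
#' @param include_latent also write the `latent_*` ground-truth columns.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, include_latent = FALSE) {
  cols <- .cohort_columns
  if (include_latent) cols <- c(cols, intersect(.latent_columns, names(records)))
  missing <- setdiff(.cohort_columns, names(records))
  if (length(missing)) {
    stop("cohort is missing required column(s): ", paste(missing, collapse = ", "))
  }
  write.csv(records[cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a pregnancy cohort CSV
#'
#' Re-reads a file produced by [write_cohort()] (or an externally assembled
#' cohort with the same header).  Records failing the gestational-age
#' inclusion window or basic plausibility checks raise a validation error
#' naming the offending record ids.  Missing biometry cells are kept as
#' `NA`: such records stay in the cohort and are excluded later, per
#' standard, when a formula actually needs the measurement (see
#' [incomplete_biometry()]).
#'
#' @param path CSV file path.
#' @return a validated `pregnancy_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  x <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("malformed cohort CSV: ", conditionMessage(e), call. = FALSE)
  )
  missing <- setdiff(.cohort_columns, names(x))
  if (length(missing)) {
    stop("cohort CSV is missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (f in c("smoker", .apo_components)) x[[f]] <- as.logical(x[[f]])
  for (f in c("ga_scan_days", "ga_delivery_days", "birthweight_g")) {
    x[[f]] <- as.integer(x[[f]])
  }
  validate_cohort(x)
}

#' Validate cohort records
#'
#' Enforces the record invariants: scan gestational age in 238-258 days
#' (34+0 to 36+6), delivery in 259-294 days (37+0 to 42+0), delivery after
#' the scan, positive birthweight, and positive biometry where present.
#'
#' @param records cohort data.frame.
#' @return the records, invisibly classed as `pregnancy_cohort`.
#' @export
validate_cohort <- function(records) {
  fail <- function(cond, what) {
    bad <- which(cond)
    if (length(bad)) {
      ids <- records$record_id[bad]
      stop(sprintf("invalid cohort record(s) [%s]: %s",
                   paste(utils::head(ids, 5), collapse = ", "), what),
           call. = FALSE)
    }
  }
  fail(is.na(records$ga_scan_days) | records$ga_scan_days < 238 |
         records$ga_scan_days > 258,
       "ga_scan_days must lie in 238-258 days (34+0 to 36+6 weeks)")
  fail(is.na(records$ga_delivery_days) | records$ga_delivery_days < 259 |
         records$ga_delivery_days > 294,
       "ga_delivery_days must lie in 259-294 days (37+0 to 42+0 weeks)")
  fail(records$ga_delivery_days <= records$ga_scan_days,
       "delivery must occur after the scan")
  fail(is.na(records$birthweight_g) | records$birthweight_g <= 0,
       "birthweight_g must be positive")
  for (f in c("bpd_mm", "hc_mm", "ac_mm", "fl_mm")) {
    fail(!is.na(records[[f]]) & records[[f]] <= 0,
         paste0(f, " must be positive when present"))
  }
  fail(duplicated(records$record_id), "duplicate record_id")
  if (!inherits(records, "pregnancy_cohort")) {
    class(records) <- c("pregnancy_cohort", class(records))
  }
  invisible(records)
}

#' Flag records with incomplete biometry
#'
#' @param records cohort data.frame.
#' @return a data.frame with `record_id` and `missing` (comma-separated
#'   missing measurement names) for records lacking any of BPD, HC, AC, FL.
#' @export
incomplete_biometry <- function(records) {
  m <- sapply(c("bpd_mm", "hc_mm", "ac_mm", "fl_mm"), function(f) is.na(records[[f]]))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(records))
  any_missing <- rowSums(m) > 0
  data.frame(
    record_id = records$record_id[any_missing],
    missing = apply(m[any_missing, , drop = FALSE], 1, function(r) {
      paste(sub("_mm$", "", c("bpd_mm", "hc_mm", "ac_mm", "fl_mm")[r]), collapse = ",")
    }),
    stringsAsFactors = FALSE
  )
}
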