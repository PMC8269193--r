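## SGA gold standard and adverse perinatal outcome (APO) flags.

#' Construct a birthweight reference grid
#'
#' The gold standard for SGA: a 10th-percentile birthweight per gestational
#' age at delivery (and newborn sex, when available).
#'
#' @param ga_grid integer days spanning the delivery envelope (259-294).
#' @param p10_weight numeric grams, either a vector (pooled reference,
#'   one value per GA) or a matrix/data.frame with columns `male`,
#'   `female`.
#' @return object of class `bw_reference`.
#' @export
birthweight_reference <- function(ga_grid, p10_weight) {
  ga_grid <- as.integer(ga_grid)
  stopifnot(!is.unsorted(ga_grid, strictly = TRUE))
  if (is.null(dim(p10_weight))) {
    p10_weight <- cbind(pooled = as.numeric(p10_weight))
  } else {
    p10_weight <- as.matrix(as.data.frame(p10_weight))
  }
  stopifnot(nrow(p10_weight) == length(ga_grid))
  if (any(apply(p10_weight, 2, function(cl) any(diff(cl) < 0)))) {
    stop("reference P10 weights must be nondecreasing in gestational age")
  }
  structure(list(ga_grid = ga_grid, p10_weight = p10_weight,
                 sex_specific = all(c("male", "female") %in% colnames(p10_weight))),
            class = "bw_reference")
}

#' Birthweight reference implied by a generator configuration
#'
#' Derives the 10th-percentile cut grid from the generator's true
#' birthweight distribution, placed at the configured `target_sga_rate`
#' quantile so the population SGA proportion equals that target.  The grid
#' is sex-specific, mirroring the sex-specific weight distribution.
#'
#' @param config a [cohort_config()].
#' @return a `bw_reference` spanning the delivery envelope.
#' @export
reference_from_config <- function(config) {
  ga <- seq(config$delivery_ga_range[1], config$delivery_ga_range[2])
  zq <- qnorm(config$target_sga_rate)
  med <- curve_median(ga, config$growth_curve)
  birthweight_reference(ga, cbind(
    male = med * exp(config$sex_effect_log) * exp(config$birthweight_sd_log * zq),
    female = med * exp(-config$sex_effect_log) * exp(config$birthweight_sd_log * zq)
  ))
}

#' Classify a delivery as small for gestational age
#'
#' True iff the birthweight is strictly below the (linearly
#' GA-interpolated) 10th-percentile reference weight for that sex; exact
#' equality is not SGA.
#'
#' @param birthweight_g birthweight(s), grams.
#' @param ga_delivery_days gestational age(s) at delivery, days; must lie
#'   within the reference span.
#' @param sex `"male"`/`"female"` (ignored by pooled references).
#' @param reference a [birthweight_reference()].
#' @return logical vector.
#' @export
classify_sga <- function(birthweight_g, ga_delivery_days, sex, reference) {
  stopifnot(inherits(reference, "bw_reference"))
  if (any(ga_delivery_days < min(reference$ga_grid) |
            ga_delivery_days > max(reference$ga_grid))) {
    stop("gestational age at delivery outside the reference span")
  }
  n <- max(length(birthweight_g), length(ga_delivery_days), length(sex))
  birthweight_g <- rep_len(birthweight_g, n)
  ga_delivery_days <- rep_len(ga_delivery_days, n)
  sex <- rep_len(sex, n)
  cut <- numeric(n)
  if (reference$sex_specific) {
    for (s in c("male", "female")) {
      idx <- sex == s
      if (any(idx)) {
        cut[idx] <- approx(reference$ga_grid, reference$p10_weight[, s],
                           xout = ga_delivery_days[idx])$y
      }
    }
  } else {
    cut <- approx(reference$ga_grid, reference$p10_weight[, 1],
                  xout = ga_delivery_days)$y
  }
  birthweight_g < cut
}

#' Derive outcome flags for a cohort
#'
#' Copies the five APO component flags, enforces the composite
#' `any_apo` (their union; SGA itself is not an APO), and classifies SGA
#' against the reference.
#'
#' @param records cohort data.frame.
#' @param reference a [birthweight_reference()].
#' @return data.frame with `record_id`, `sga`, the five component flags and
#'   `any_apo`.
#' @export
derive_outcomes <- function(records, reference) {
  flags <- records[.apo_components]
  data.frame(
    record_id = records$record_id,
    sga = classify_sga(records$birthweight_g, records$ga_delivery_days,
                       records$sex, reference),
    flags,
    any_apo = Reduce(`|`, flags),
    stringsAsFactors = FALSE
  )
}

#' Write a birthweight reference grid to CSV
#' @param reference a `bw_reference`.
#' @param path output path; long format `ga_days, sex, level, weight_g`.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  cols <- colnames(reference$p10_weight)
  out <- do.call(rbind, lapply(cols, function(s) {
    data.frame(ga_days = reference$ga_grid, sex = s, level = 10,
               weight_g = reference$p10_weight[, s])
  }))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a birthweight reference grid from CSV
#' @param path file written by [write_reference()].
#' @return a `bw_reference`.
#' @export
read_reference <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x <- x[x$level == 10, ]
  ga <- sort(unique(x$ga_days))
  mat <- sapply(unique(x$sex), function(s) {
    xs <- x[x$sex == s, ]
    xs$weight_g[match(ga, xs$ga_days)]
  })
  birthweight_reference(ga, mat)
}
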