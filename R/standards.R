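## Growth-standard percentile engines.
##
## A growth standard converts an EFW at a scan gestational age (plus
## maternal covariates, when customized) into an estimated percentile
## weight (EPW).  Three parameterization families cover the standards
## compared here:
##   * zscore_curve  - a median weight curve with a GA-dependent dispersion
##                     (non-customized population standards);
##   * customized    - a Gardosi-style individualized expected weight:
##                     (term optimal weight + covariate effects) scaled by a
##                     proportionality curve, with a coefficient of
##                     variation;
##   * quantile_grid - tabulated weights at fixed percentile levels,
##                     interpolated linearly in GA and on the probit scale
##                     in weight (the WHO-chart representation).

.percentile_floor <- 0.01
.percentile_ceiling <- 99.99

#' Construct a growth-standard specification
#'
#' @param standard_id identifier, e.g. `"msuh_nc"`.
#' @param family `"zscore_curve"`, `"customized"` or `"quantile_grid"`.
#' @param efw_formula_id registered EFW formula this standard was built
#'   with; EFW is always computed with the formula of its own standard.
#' @param parameters family-specific parameter block (see Details).
#' @param citation source/provenance string.
#' @param label human-readable display name.
#' @param version free-form version tag for run manifests.
#'
#' @details
#' `zscore_curve` parameters: `median_curve` (log-quadratic curve, see
#' [curve_median()], with optional calibration `scale_log`), `dispersion`
#' (`transform = "log"` with `sigma_log`, or `transform = "identity"` with
#' `cv`), optional `ga_range` envelope (days, default 238-258).
#'
#' `customized` parameters: `base_term_weight_g`, `proportionality` curve,
#' `dispersion` (identity/CV), `scale` (calibration multiplier, default 1)
#' and `covariate_effects`: a named list of additive gram effects, each
#' either `list(type = "linear", ref =, per_unit =)` or
#' `list(type = "categorical", ref =, effects = list(...))`.  The reference
#' profile has total adjustment zero by construction.
#'
#' `quantile_grid` parameters: `ga_grid` (days, ascending), `levels`
#' (percentiles, e.g. 5...95), `weights` (matrix, rows = GA nodes,
#' columns = levels, strictly increasing along both).
#'
#' @return an object of class `growth_standard`.
#' @export
growth_standard <- function(standard_id, family, efw_formula_id, parameters,
                            citation = "", label = standard_id, version = "1") {
  family <- match.arg(family, c("zscore_curve", "customized", "quantile_grid"))
  spec <- structure(
    list(standard_id = standard_id, family = family,
         efw_formula_id = efw_formula_id, parameters = parameters,
         customization_covariates =
           if (family == "customized") names(parameters$covariate_effects) else character(),
         citation = citation, label = label, version = version),
    class = "growth_standard"
  )
  validate_standard(spec)
}

#' Validate a growth-standard specification
#'
#' Structural checks run at load time, not call time: parameter block
#' completeness, positive dispersion, median curve positive and
#' nondecreasing over the scan envelope, strict grid monotonicity in level
#' and GA, and customized standards declaring at least one covariate.
#'
#' @param spec a `growth_standard` object.
#' @return the spec, invisibly.
#' @export
validate_standard <- function(spec) {
  p <- spec$parameters
  if (spec$family == "zscore_curve") {
    stopifnot(!is.null(p$median_curve), !is.null(p$dispersion))
    ga <- standard_ga_range(spec)
    med <- curve_median(seq(ga[1], ga[2]), p$median_curve)
    if (any(med <= 0) || any(diff(med) < 0)) {
      stop(sprintf("standard '%s': median curve must be positive and nondecreasing over %d-%d days",
                   spec$standard_id, ga[1], ga[2]))
    }
    check_dispersion(spec, p$dispersion)
  } else if (spec$family == "customized") {
    stopifnot(is.numeric(p$base_term_weight_g), p$base_term_weight_g > 0,
              !is.null(p$proportionality), !is.null(p$dispersion))
    ga <- standard_ga_range(spec)
    pr <- proportionality(seq(ga[1], ga[2]), p$proportionality)
    if (any(pr <= 0) || any(pr > 1 + 1e-9) || any(diff(pr) < 0)) {
      stop(sprintf("standard '%s': proportionality must lie in (0, 1] and be nondecreasing over the scan envelope",
                   spec$standard_id))
    }
    check_dispersion(spec, p$dispersion)
    if (length(p$covariate_effects) < 1) {
      stop(sprintf("standard '%s': customized standards must declare at least one covariate", spec$standard_id))
    }
  } else {
    w <- p$weights
    if (!is.matrix(w)) stop(sprintf("standard '%s': grid weights must be a matrix", spec$standard_id))
    if (length(p$ga_grid) != nrow(w) || length(p$levels) != ncol(w)) {
      stop(sprintf("standard '%s': grid dimensions do not match ga_grid/levels", spec$standard_id))
    }
    if (any(apply(w, 1, function(r) any(diff(r) <= 0)))) {
      stop(sprintf("standard '%s': grid weights must be strictly increasing in level at every GA",
                   spec$standard_id))
    }
    if (any(apply(w, 2, function(cl) any(diff(cl) <= 0)))) {
      stop(sprintf("standard '%s': grid weights must be increasing in GA at every level",
                   spec$standard_id))
    }
  }
  invisible(spec)
}

check_dispersion <- function(spec, d) {
  ok <- (identical(d$transform, "log") && is.numeric(d$sigma_log) && d$sigma_log > 0) ||
    (identical(d$transform, "identity") && is.numeric(d$cv) && d$cv > 0)
  if (!ok) {
    stop(sprintf("standard '%s': dispersion must declare transform 'log' (sigma_log > 0) or 'identity' (cv > 0)",
                 spec$standard_id))
  }
}

standard_ga_range <- function(spec) {
  p <- spec$parameters
  if (!is.null(p$ga_range)) return(p$ga_range)
  if (spec$family == "quantile_grid") return(range(p$ga_grid))
  c(238, 258)
}

check_ga_envelope <- function(ga_days, spec) {
  r <- standard_ga_range(spec)
  if (any(ga_days < r[1] | ga_days > r[2])) {
    stop(sprintf("gestational age outside the %d-%d day envelope of standard '%s'",
                 r[1], r[2], spec$standard_id))
  }
}

## ---- family engines --------------------------------------------------------

#' Percentile under a z-score-curve standard
#'
#' `z = (t(efw) - t(median(ga))) / scale(ga)` where `t` is the declared
#' transform (log, or identity with a coefficient-of-variation scale), and
#' the percentile is `100 * pnorm(z)` clamped to \[0.01, 99.99\].
#'
#' @param efw_g estimated fetal weight(s), grams.
#' @param ga_days gestational age(s) at scan, days.
#' @param params the `parameters` block of a `zscore_curve` standard (or a
#'   full `growth_standard`, from which it is taken).
#' @return list with `percentile` and `zscore` vectors.
#' @export
epw_zscore <- function(efw_g, ga_days, params) {
  spec <- as_zscore_spec(params)
  check_ga_envelope(ga_days, spec)
  if (any(efw_g <= 0)) stop("efw_g must be strictly positive")
  p <- spec$parameters
  med <- curve_median(ga_days, p$median_curve)
  z <- if (identical(p$dispersion$transform, "log")) {
    (log(efw_g) - log(med)) / p$dispersion$sigma_log
  } else {
    (efw_g - med) / (p$dispersion$cv * med)
  }
  list(percentile = clamp(100 * pnorm(z), .percentile_floor, .percentile_ceiling),
       zscore = z)
}

as_zscore_spec <- function(params) {
  if (inherits(params, "growth_standard")) return(params)
  growth_standard("anonymous", "zscore_curve", "hadlock4", params)
}

#' Percentile under a Gardosi-style customized standard
#'
#' The individualized expected weight at the scan is
#' `scale * (base_term_weight + sum of covariate effects) *
#' proportionality(ga)`; the z-score and percentile then follow the
#' z-score-curve recipe with this expectation as the centre.
#'
#' @param efw_g estimated fetal weight(s), grams.
#' @param ga_days gestational age(s), days.
#' @param profile data.frame (one row per efw) or named list of covariate
#'   values; must supply every declared customization covariate.
#' @param params `parameters` block of a `customized` standard, or the
#'   standard itself.
#' @return list with `percentile`, `zscore` and `expected_g`.
#' @export
epw_customized <- function(efw_g, ga_days, profile, params) {
  spec <- if (inherits(params, "growth_standard")) params else
    growth_standard("anonymous", "customized", "hadlock4", params)
  check_ga_envelope(ga_days, spec)
  if (any(efw_g <= 0)) stop("efw_g must be strictly positive")
  p <- spec$parameters
  eff <- covariate_adjustment(profile, p$covariate_effects, n = length(efw_g))
  scale <- if (is.null(p$scale)) 1 else p$scale
  expected <- scale * (p$base_term_weight_g + eff) *
    proportionality(ga_days, p$proportionality)
  z <- if (identical(p$dispersion$transform, "log")) {
    (log(efw_g) - log(expected)) / p$dispersion$sigma_log
  } else {
    (efw_g - expected) / (p$dispersion$cv * expected)
  }
  list(percentile = clamp(100 * pnorm(z), .percentile_floor, .percentile_ceiling),
       zscore = z, expected_g = expected)
}

## Sum of additive gram effects for a covariate profile; errors naming any
## covariate the profile does not supply.
covariate_adjustment <- function(profile, effects, n = 1) {
  if (is.null(profile)) profile <- list()
  total <- numeric(n)
  for (nm in names(effects)) {
    e <- effects[[nm]]
    v <- profile[[nm]]
    if (is.null(v) || any(is.na(v))) {
      stop(sprintf("missing covariate '%s' required for customization", nm))
    }
    v <- rep_len(v, n)
    total <- total + if (identical(e$type, "linear")) {
      e$per_unit * (as.numeric(v) - e$ref)
    } else {
      vapply(as.character(v), function(val) {
        if (identical(val, as.character(e$ref))) 0
        else if (!is.null(e$effects[[val]])) e$effects[[val]]
        else stop(sprintf("unknown level '%s' for covariate '%s'", val, nm))
      }, numeric(1), USE.NAMES = FALSE)
    }
  }
  total
}

#' Percentile under a quantile-grid standard
#'
#' Weights at the seven tabulated levels are first interpolated linearly in
#' gestational age between the weekly grid nodes; the percentile is then
#' obtained by interpolating the probit of the level linearly in weight
#' between the bracketing levels.  Outside the outermost levels the probit
#' line through the two outermost nodes is extrapolated, and the result is
#' clamped to \[0.01, 99.99\].
#'
#' @param efw_g estimated fetal weight(s), grams.
#' @param ga_days gestational age(s), days; must lie within the grid span.
#' @param grid `parameters` block of a `quantile_grid` standard (fields
#'   `ga_grid`, `levels`, `weights`), or the standard itself.
#' @return list with `percentile` (and `zscore = NA`, as the family has no
#'   z-score).
#' @export
epw_quantile_grid <- function(efw_g, ga_days, grid) {
  spec <- if (inherits(grid, "growth_standard")) grid else
    growth_standard("anonymous", "quantile_grid", "hadlock4", grid)
  check_ga_envelope(ga_days, spec)
  if (any(efw_g <= 0)) stop("efw_g must be strictly positive")
  p <- spec$parameters
  n <- max(length(efw_g), length(ga_days))
  efw_g <- rep_len(efw_g, n)
  ga_days <- rep_len(ga_days, n)
  w_at <- grid_weights_at(ga_days, p)           # n x K
  y <- qnorm(p$levels / 100)                    # probits of levels
  probit <- numeric(n)
  K <- length(y)
  for (i in seq_len(n)) {
    w <- w_at[i, ]
    k <- findInterval(efw_g[i], w)              # 0 .. K
    k <- clamp(k, 1L, K - 1L)                   # extrapolate from outer segment
    probit[i] <- y[k] + (efw_g[i] - w[k]) * (y[k + 1] - y[k]) / (w[k + 1] - w[k])
  }
  list(percentile = clamp(100 * pnorm(probit), .percentile_floor, .percentile_ceiling),
       zscore = rep(NA_real_, n))
}

## Linear-in-days GA interpolation of the level weights; returns n x K.
grid_weights_at <- function(ga_days, p) {
  sapply(seq_along(p$levels), function(k) {
    approx(p$ga_grid, p$weights[, k], xout = ga_days, rule = 2)$y
  }) |> matrix(nrow = length(ga_days))
}

## ---- dispatch --------------------------------------------------------------

#' Estimated percentile weight under a standard
#'
#' Family-dispatching front end over [epw_zscore()], [epw_customized()] and
#' [epw_quantile_grid()].
#'
#' @param standard a `growth_standard`.
#' @param efw_g estimated fetal weight(s), grams.
#' @param ga_days gestational age(s), days.
#' @param profile covariate profile (customized standards only).
#' @return list with `percentile` and `zscore`.
#' @export
epw <- function(standard, efw_g, ga_days, profile = NULL) {
  stopifnot(inherits(standard, "growth_standard"))
  switch(standard$family,
         zscore_curve = epw_zscore(efw_g, ga_days, standard),
         customized = epw_customized(efw_g, ga_days, profile, standard),
         quantile_grid = epw_quantile_grid(efw_g, ga_days, standard))
}

#' Weight at a given percentile (inverse of the percentile map)
#'
#' @param p percentile(s), strictly in (0, 100).
#' @param ga_days gestational age(s), days.
#' @param standard a `growth_standard`.
#' @param profile covariate profile for customized standards.
#' @return weight(s) in grams.  Mutual inverse of the forward percentile
#'   operation to within 0.1 percentile points away from the clamping
#'   bounds.
#' @export
weight_at_percentile <- function(p, ga_days, standard, profile = NULL) {
  stopifnot(inherits(standard, "growth_standard"))
  if (any(p <= 0 | p >= 100)) stop("percentile must lie strictly in (0, 100)")
  check_ga_envelope(ga_days, standard)
  z <- qnorm(p / 100)
  par <- standard$parameters
  if (standard$family == "zscore_curve") {
    med <- curve_median(ga_days, par$median_curve)
    if (identical(par$dispersion$transform, "log")) {
      med * exp(par$dispersion$sigma_log * z)
    } else {
      med * (1 + par$dispersion$cv * z)
    }
  } else if (standard$family == "customized") {
    eff <- covariate_adjustment(profile, par$covariate_effects,
                                n = max(length(p), length(ga_days)))
    scale <- if (is.null(par$scale)) 1 else par$scale
    expected <- scale * (par$base_term_weight_g + eff) *
      proportionality(ga_days, par$proportionality)
    if (identical(par$dispersion$transform, "log")) {
      expected * exp(par$dispersion$sigma_log * z)
    } else {
      expected * (1 + par$dispersion$cv * z)
    }
  } else {
    w_at <- grid_weights_at(ga_days, par)
    y <- qnorm(par$levels / 100)
    n <- max(length(p), length(ga_days))
    z <- rep_len(z, n)
    out <- numeric(n)
    K <- length(y)
    for (i in seq_len(n)) {
      w <- w_at[if (nrow(w_at) == 1) 1 else i, ]
      k <- clamp(findInterval(z[i], y), 1L, K - 1L)
      out[i] <- w[k] + (z[i] - y[k]) * (w[k + 1] - w[k]) / (y[k + 1] - y[k])
    }
    out
  }
}

## ---- cohort-level dispatch -------------------------------------------------

#' Estimated percentile weight for every record under every standard
#'
#' For each standard the EFW is computed with that standard's declared
#' formula, then converted to a percentile via the family-appropriate
#' engine.  Records lacking a measurement the formula needs, or a covariate
#' the customization needs, are marked excluded for that standard only and
#' keep contributing to the standards they support.
#'
#' @param records cohort data.frame (see [generate_cohort()]).
#' @param standards named list of `growth_standard`s; defaults to the six
#'   bundled standards.
#' @return a long data.frame with columns `record_id`, `standard_id`,
#'   `efw_g`, `percentile`, `zscore`, `excluded`, `reason`.  The
#'   per-standard exclusion tally is attached as attribute `"exclusions"`.
#' @export
epw_all_standards <- function(records, standards = bundled_standards()) {
  stopifnot(length(standards) > 0)
  out <- vector("list", length(standards))
  excl <- setNames(integer(length(standards)), vapply(standards, `[[`, "", "standard_id"))
  for (si in seq_along(standards)) {
    std <- standards[[si]]
    formula <- get_efw_formula(std$efw_formula_id)
    n <- nrow(records)
    excluded <- rep(FALSE, n)
    reason <- rep(NA_character_, n)
    for (m in formula$required_measurements) {
      miss <- is.na(records[[paste0(m, "_mm")]])
      reason[miss & !excluded] <- paste0("incomplete_biometry:", m)
      excluded <- excluded | miss
    }
    for (cv in std$customization_covariates) {
      col <- records[[cv]]
      miss <- if (is.null(col)) rep(TRUE, n) else is.na(col)
      reason[miss & !excluded] <- paste0("missing_covariate:", cv)
      excluded <- excluded | miss
    }
    efw_g <- rep(NA_real_, n)
    percentile <- rep(NA_real_, n)
    zscore <- rep(NA_real_, n)
    keep <- !excluded
    if (any(keep)) {
      efw_g[keep] <- efw(formula, records[keep, , drop = FALSE])
      res <- epw(std, efw_g[keep], records$ga_scan_days[keep],
                 profile = records[keep, , drop = FALSE])
      percentile[keep] <- res$percentile
      zscore[keep] <- res$zscore
    }
    excl[si] <- sum(excluded)
    out[[si]] <- data.frame(record_id = records$record_id,
                            standard_id = std$standard_id,
                            efw_g = efw_g, percentile = percentile,
                            zscore = zscore, excluded = excluded,
                            reason = reason, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "exclusions") <- data.frame(standard_id = names(excl),
                                        excluded = as.integer(excl),
                                        analyzed = nrow(records) - as.integer(excl),
                                        row.names = NULL)
  res
}

## ---- calibration -----------------------------------------------------------

#' Calibrate a standard's location and dispersion to cohort percentile targets
#'
#' Adjusts a standard so that, on the supplied cohort, the 10th, 50th and
#' 90th percentiles of its estimated percentile weights land on the target
#' values (the median exactly, the outer pair through the fitted spread).
#' This is the documented route by which the bundled parameter files were
#' produced: source publications for several standards do not print usable
#' coefficient tables, so each bundled file records the family, formula and
#' covariate structure from its source, with location/dispersion fitted to
#' the cohort-summary calibration targets.
#'
#' @param standard a `growth_standard`.
#' @param records calibration cohort data.frame.
#' @param targets numeric `c(p10, p50, p90)`: the cohort EPW distribution
#'   summary the calibrated standard should reproduce (percentile units).
#' @return the recalibrated `growth_standard`.
#' @export
calibrate_standard <- function(standard, records, targets) {
  stopifnot(length(targets) == 3, all(targets > 0), all(targets < 100),
            !is.unsorted(targets))
  zt <- qnorm(targets / 100)         # targets ordered p10 < p50 < p90
  formula <- get_efw_formula(standard$efw_formula_id)
  ok <- rep(TRUE, nrow(records))
  for (m in formula$required_measurements) ok <- ok & !is.na(records[[paste0(m, "_mm")]])
  for (cv in standard$customization_covariates) ok <- ok & !is.na(records[[cv]])
  rec <- records[ok, , drop = FALSE]
  efw_g <- efw(formula, rec)
  par <- standard$parameters
  if (standard$family == "zscore_curve" || standard$family == "quantile_grid") {
    curve <- if (standard$family == "quantile_grid") par$source_curve else par$median_curve
    curve$scale_log <- 0
    w <- log(efw_g) - log(curve_median(rec$ga_scan_days, curve))
    q <- quantile(w, c(0.1, 0.5, 0.9), names = FALSE)
    sigma <- (q[3] - q[1]) / (zt[3] - zt[1])
    shift <- q[2] - sigma * zt[2]
    if (standard$family == "zscore_curve") {
      par$median_curve$scale_log <- shift
      par$dispersion <- list(transform = "log", sigma_log = sigma)
    } else {
      curve$scale_log <- shift
      par$source_curve <- curve
      par$weights <- outer(curve_median(par$ga_grid, curve),
                           exp(sigma * qnorm(par$levels / 100)))
      rownames(par$weights) <- NULL
    }
  } else {
    par0 <- par
    par0$scale <- 1
    eff <- covariate_adjustment(rec, par$covariate_effects, n = nrow(rec))
    expected0 <- (par$base_term_weight_g + eff) *
      proportionality(rec$ga_scan_days, par$proportionality)
    r <- efw_g / expected0
    q <- quantile(r, c(0.1, 0.5, 0.9), names = FALSE)
    A <- zt[2]; B <- zt[3] - zt[1]; D <- q[3] - q[1]
    cv <- D / (q[2] * B - D * A)
    lambda <- q[2] / (1 + cv * A)
    par$scale <- lambda
    par$dispersion <- list(transform = "identity", cv = cv)
  }
  standard$parameters <- par
  validate_standard(standard)
  standard
}

## ---- persistence -----------------------------------------------------------

#' Write a growth standard to a JSON parameter file
#' @param standard a `growth_standard`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standard <- function(standard, path) {
  x <- unclass(standard)
  if (standard$family == "quantile_grid") {
    x$parameters$weights <- apply(standard$parameters$weights, 1, identity, simplify = FALSE)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a growth standard from a JSON parameter file
#' @param path JSON file written by [write_standard()] (or hand-authored
#'   with the same schema).
#' @return a validated `growth_standard`.
#' @export
load_standard <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$family, "quantile_grid")) {
    w <- x$parameters$weights
    if (is.list(w)) w <- do.call(rbind, w)
    x$parameters$weights <- matrix(as.numeric(w), nrow = length(x$parameters$ga_grid),
                                   byrow = FALSE)
  }
  if (identical(x$family, "customized")) {
    ## jsonlite simplification can turn effect lists into vectors; re-list.
    x$parameters$covariate_effects <- lapply(x$parameters$covariate_effects, function(e) {
      e <- as.list(e)
      if (!is.null(e$effects)) e$effects <- as.list(e$effects)
      e
    })
  }
  growth_standard(standard_id = x$standard_id, family = x$family,
                  efw_formula_id = x$efw_formula_id,
                  parameters = x$parameters,
                  citation = if (is.null(x$citation)) "" else x$citation,
                  label = if (is.null(x$label)) x$standard_id else x$label,
                  version = if (is.null(x$version)) "1" else x$version)
}

#' The six bundled growth standards
#'
#' Loads the bundled parameter files: the non-customized and customized
#' MSUH-type standards, the Figueras-type customized standard, the
#' INTERGROWTH-21st-type standard (Stirnemann HC/AC formula), the WHO-type
#' quantile grid and the FMF-type standard (Hadlock HC/AC/FL formula).
#' Location and dispersion in these files are calibration fits, not
#' transcriptions (see [calibrate_standard()]).
#'
#' @param dir directory of standard JSON files; defaults to the bundled set.
#' @return named list of `growth_standard`s.
#' @export
bundled_standards <- function(dir = system.file("extdata", "standards",
                                                package = "epwscreen")) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no standard parameter files found in ", dir)
  stds <- lapply(files, load_standard)
  ord <- c("msuh_nc", "msuh_cust", "figueras", "intergrowth21", "who", "fmf")
  names(stds) <- vapply(stds, `[[`, "", "standard_id")
  stds[order(match(names(stds), ord))]
}

#' Export a standard's chart: weights at the classic levels across the scan window
#'
#' @param standard a `growth_standard`.
#' @param ga_days days to tabulate (default 238-258).
#' @param levels percentile levels.
#' @param profile covariate profile for customized standards (default: the
#'   reference profile, i.e. zero adjustment).
#' @return data.frame with `ga_days` and one `p<level>` column per level.
#' @export
standard_chart <- function(standard, ga_days = 238:258,
                           levels = c(5, 10, 25, 50, 75, 90, 95),
                           profile = NULL) {
  if (standard$family == "customized" && is.null(profile)) {
    profile <- reference_profile(standard)
  }
  out <- data.frame(ga_days = ga_days)
  for (l in levels) {
    out[[paste0("p", l)]] <- weight_at_percentile(rep(l, length(ga_days)),
                                                  ga_days, standard, profile)
  }
  out
}

#' Reference covariate profile of a customized standard (zero adjustment)
#' @param standard a customized `growth_standard`.
#' @return one-row data.frame of reference covariate values.
#' @export
reference_profile <- function(standard) {
  eff <- standard$parameters$covariate_effects
  as.data.frame(lapply(eff, function(e) e$ref), stringsAsFactors = FALSE,
                col.names = names(eff))
}

#' @export
print.growth_standard <- function(x, ...) {
  cat(sprintf("Growth standard '%s' (%s family, EFW formula '%s')\n",
              x$standard_id, x$family, x$efw_formula_id))
  if (length(x$customization_covariates)) {
    cat("  customized for:", paste(x$customization_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}
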