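## Estimated fetal weight (EFW) from ultrasound biometry.
##
## Formulas are kept in a registry so that each growth standard can declare
## the regression it was built with.  Coefficients live in JSON parameter
## files under inst/extdata/formulas (transcribed from the cited source
## publications), never in code.

.efw_registry <- new.env(parent = emptyenv())

.efw_measurements <- c("bpd", "hc", "ac", "fl")

#' Construct an EFW formula specification
#'
#' An EFW formula maps a set of fetal biometry measurements to an estimated
#' weight in grams.  Two functional forms are supported: `"log10_poly"`, a
#' linear model for log10(weight) in products of measurements in centimetres
#' (the Hadlock family), and `"stirnemann"`, the log-linear
#' cephalic/abdominal-circumference model used by the INTERGROWTH-21st
#' project.
#'
#' @param formula_id unique identifier, e.g. `"hadlock4"`.
#' @param form `"log10_poly"` or `"stirnemann"`.
#' @param required_measurements character subset of
#'   `c("bpd", "hc", "ac", "fl")`.
#' @param coefficients for `"log10_poly"`: a list of terms, each a list with
#'   `coef` (numeric) and `vars` (character vector of measurement names,
#'   possibly empty for the intercept).  For `"stirnemann"`: a named list
#'   with `c0`, `c_ac3`, `c_ac3_log_ac`, `c_hc`.
#' @param units unit the coefficients expect; always converted from the
#'   millimetre API internally. `"cm"` for the Hadlock family, `"m"` for
#'   the Stirnemann model.
#' @param citation source publication string.
#' @return an object of class `efw_formula`.
#' @seealso [register_formula()], [efw()]
#' @export
efw_formula <- function(formula_id, form, required_measurements, coefficients,
                        units = c("cm", "m"), citation = "") {
  units <- match.arg(units)
  stopifnot(is.character(formula_id), length(formula_id) == 1, nzchar(formula_id))
  form <- match.arg(form, c("log10_poly", "stirnemann"))
  if (length(required_measurements) == 0) {
    stop("an EFW formula must declare at least one required measurement")
  }
  bad <- setdiff(required_measurements, .efw_measurements)
  if (length(bad)) {
    stop("unknown measurement(s): ", paste(bad, collapse = ", "))
  }
  if (form == "log10_poly") {
    ok <- is.list(coefficients) && length(coefficients) > 0 &&
      all(vapply(coefficients, function(t) {
        is.numeric(t$coef) && length(t$coef) == 1 &&
          (length(t$vars) == 0 || all(t$vars %in% required_measurements))
      }, logical(1)))
    if (!ok) stop("incomplete coefficients for form 'log10_poly'")
  } else {
    need <- c("c0", "c_ac3", "c_ac3_log_ac", "c_hc")
    if (!all(need %in% names(coefficients))) {
      stop("incomplete coefficients for form 'stirnemann': need ",
           paste(need, collapse = ", "))
    }
  }
  structure(
    list(formula_id = formula_id,
         form = form,
         required_measurements = as.character(required_measurements),
         coefficients = coefficients,
         units = units,
         citation = citation),
    class = "efw_formula"
  )
}

#' Register an EFW formula for lookup by id
#'
#' @param spec an [efw_formula()] object.
#' @param overwrite replace an existing entry instead of erroring.
#' @return the registered spec, invisibly.
#' @export
register_formula <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "efw_formula"))
  if (!overwrite && !is.null(.efw_registry[[spec$formula_id]])) {
    stop(sprintf("EFW formula '%s' is already registered", spec$formula_id))
  }
  assign(spec$formula_id, spec, envir = .efw_registry)
  invisible(spec)
}

#' Retrieve a registered EFW formula
#'
#' @param formula_id identifier used at registration.
#' @return the `efw_formula` object.
#' @export
get_efw_formula <- function(formula_id) {
  spec <- .efw_registry[[formula_id]]
  if (is.null(spec)) {
    stop(sprintf("no EFW formula registered under id '%s'", formula_id))
  }
  spec
}

#' List registered EFW formula ids
#' @return character vector of ids.
#' @export
list_efw_formulas <- function() sort(ls(.efw_registry))

#' Read an EFW formula from a JSON parameter file
#'
#' @param path JSON file with fields `formula_id`, `form`,
#'   `required_measurements`, `coefficients`, `units`, `citation`.
#' @return an `efw_formula` object (not yet registered).
#' @export
load_efw_formula <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  coefs <- x$coefficients
  if (identical(x$form, "log10_poly")) {
    coefs <- lapply(coefs, function(t) {
      list(coef = as.numeric(t$coef), vars = as.character(unlist(t$vars)))
    })
  } else {
    coefs <- lapply(coefs, as.numeric)
  }
  efw_formula(
    formula_id = x$formula_id,
    form = x$form,
    required_measurements = as.character(unlist(x$required_measurements)),
    coefficients = coefs,
    units = x$units,
    citation = if (is.null(x$citation)) "" else x$citation
  )
}

register_builtin_formulas <- function(overwrite = FALSE) {
  dir <- system.file("extdata", "formulas", package = "epwscreen")
  if (dir == "") return(invisible(NULL))
  for (f in list.files(dir, pattern = "\\.json$", full.names = TRUE)) {
    register_formula(load_efw_formula(f), overwrite = overwrite)
  }
  invisible(NULL)
}

## Extract a named measurement matrix (mm) from a data.frame or named vector.
## Columns may be named "ac" or "ac_mm".
biometry_matrix <- function(biometry, required) {
  get_col <- function(nm) {
    if (is.data.frame(biometry) || is.list(biometry)) {
      if (!is.null(biometry[[paste0(nm, "_mm")]])) return(biometry[[paste0(nm, "_mm")]])
      if (!is.null(biometry[[nm]])) return(biometry[[nm]])
    } else if (is.numeric(biometry)) {
      nms <- names(biometry)
      if (paste0(nm, "_mm") %in% nms) return(unname(biometry[[paste0(nm, "_mm")]]))
      if (nm %in% nms) return(unname(biometry[[nm]]))
    }
    NULL
  }
  cols <- lapply(required, get_col)
  missing <- required[vapply(cols, is.null, logical(1))]
  if (length(missing)) {
    stop(sprintf("incomplete biometry: missing measurement(s) %s",
                 paste(missing, collapse = ", ")))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- required
  m
}

#' Estimated fetal weight from biometry
#'
#' Evaluates an EFW regression formula.  Measurements are supplied in
#' millimetres (columns `bpd_mm`, `hc_mm`, `ac_mm`, `fl_mm`, or the bare
#' names); unit conversion to the formula's native unit happens internally.
#'
#' @param formula an `efw_formula` object or a registered formula id.
#' @param biometry data.frame, list or named numeric vector holding the
#'   required measurements in millimetres; vectors recycle row-wise.
#' @return numeric vector of estimated weights in grams.
#' @export
#' @examples
#' efw("hadlock4", c(bpd_mm = 87, hc_mm = 315, ac_mm = 305, fl_mm = 68))
efw <- function(formula, biometry) {
  if (is.character(formula)) formula <- get_efw_formula(formula)
  stopifnot(inherits(formula, "efw_formula"))
  m <- biometry_matrix(biometry, formula$required_measurements)
  if (any(!is.na(m) & m <= 0)) {
    stop("biometry measurements must be strictly positive")
  }
  ## mm -> native unit
  m <- m / switch(formula$units, cm = 10, m = 1000)
  if (formula$form == "log10_poly") {
    lw <- numeric(nrow(m))
    for (term in formula$coefficients) {
      contrib <- rep(term$coef, nrow(m))
      for (v in term$vars) contrib <- contrib * m[, v]
      lw <- lw + contrib
    }
    as.vector(10^lw)
  } else {
    cf <- formula$coefficients
    ac <- m[, "ac"]
    hc <- m[, "hc"]
    as.vector(exp(cf$c0 + cf$c_ac3 * ac^3 + cf$c_ac3_log_ac * ac^3 * log(ac) +
                    cf$c_hc * hc))
  }
}

#' @export
print.efw_formula <- function(x, ...) {
  cat(sprintf("EFW formula '%s' (%s; %s)\n", x$formula_id, x$form,
              paste(toupper(x$required_measurements), collapse = ", ")))
  if (nzchar(x$citation)) cat("  ", x$citation, "\n", sep = "")
  invisible(x)
}
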