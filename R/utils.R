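#' Clamp values to an interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Table-style rounding: 0.05 rounds up to 0.1 (for non-negative input),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x non-negative numeric vector.
#' @param digits number of decimal digits to keep.
#' @return rounded vector.
#' @export
#' @examples
#' round_half_up(21.55, 1) # 21.6
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Format a count with its percentage of a denominator
#'
#' Renders "k (p%)" cells as printed in clinical cohort tables, with
#' percentages rounded half-up to one decimal.
#'
#' @param k count (numerator).
#' @param n denominator.
#' @param digits decimal digits for the percentage.
#' @return character vector.
#' @export
#' @examples
#' count_pct_label(139, 645) # "139 (21.6%)"
count_pct_label <- function(k, n, digits = 1) {
  pct <- round_half_up(100 * k / n, digits)
  sprintf("%d (%s%%)", as.integer(k), formatC(pct, format = "f", digits = digits))
}

## Evaluate an expression under a temporary RNG seed, restoring the caller's
## RNG state afterwards.
with_preserved_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

## Configuration error naming the offending field.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}
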