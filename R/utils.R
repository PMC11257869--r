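# Calendar conventions used throughout: 365.25 days/year, 30.4375 days/month.
.DAYS_PER_YEAR <- 365.25
.DAYS_PER_MONTH <- 30.4375

#' Convert model cycles to months
#'
#' Cycles are 21 days by default; months use the 30.4375 days/month convention
#' so that 12 months equal exactly one 365.25-day year.
#'
#' @param k cycle index (0-based), vectorised
#' @param cycle_length_days length of one cycle in days
#' @return time in months at the start of cycle `k`
#' @export
cycle_to_months <- function(k, cycle_length_days = 21) {
  k * cycle_length_days / .DAYS_PER_MONTH
}

#' Convert QALYs to an equivalent number of months
#'
#' Reporting helper: one QALY corresponds to twelve months in full health,
#' so a QALY difference is expressed as `q * 12` months, rounded to one
#' decimal place.
#'
#' @param q QALYs, non-negative
#' @return months, rounded to one decimal
#' @export
qalys_to_months <- function(q) {
  if (any(q < 0)) stop("QALYs must be non-negative")
  round(q * 12, 1)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  }
  invisible(x)
}
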