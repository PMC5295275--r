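# Rounding helpers. Display values follow half-away-from-zero rounding,
# not the half-even rule of base round()/signif(), so that printed doses
# match the usual reporting convention for risk-assessment tables.

#' Round to significant figures, halves away from zero
#'
#' @param x numeric vector.
#' @param digits number of significant figures.
#' @return `x` rounded to `digits` significant figures with ties rounded
#'   away from zero.
#' @examples
#' signif_half_up(3.90625e-4, 3) # 3.91e-4
#' @export
signif_half_up <- function(x, digits = 3) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz]))) - digits + 1
  out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^e + 0.5) * 10^e
  out
}

#' Round to decimal places, halves away from zero
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Display rounding for dose values
#'
#' Doses below 0.1 mg/kg-day are reported in scientific notation with three
#' significant figures; larger doses with two decimal places. This is the
#' convention of community dose-summary tables (e.g. 3.91e-4, 9.10e-3,
#' 0.23, 5.06).
#'
#' @param x numeric dose vector.
#' @return numeric vector of display-rounded doses.
#' @export
dose_display <- function(x) {
  stopifnot(is.numeric(x))
  ifelse(is.finite(x) & abs(x) >= 0.1,
    round_half_up(x, 2),
    signif_half_up(x, 3)
  )
}

# stop with a classed domain error
abort_domain <- function(msg) {
  abort(msg, class = "ejadd_domain_error")
}

abort_validation <- function(msg) {
  abort(msg, class = "ejadd_validation_error")
}
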