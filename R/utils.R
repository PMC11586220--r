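`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ..., class = "pvsignal_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

config_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "pvsignal_config_error")
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when reporting percentages and
#' ratios in regulatory tables. `round()` in R rounds half to even, which
#' makes e.g. 0.125 -> 0.12; tables in the pharmacovigilance literature
#' round 0.125 -> 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# quantiles by linear interpolation between order statistics (stats::quantile
# type 7), on non-missing values; returns c(median, q1, q3) or NAs
median_q1_q3 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(x, probs = c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# probability vector check used by config validators
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (is.null(p) || length(p) == 0L || any(!is.finite(p)) || any(p < 0)) {
    config_error("'%s' must be a vector of non-negative finite probabilities", what)
  }
  if (abs(sum(p) - 1) > tol) {
    config_error("'%s' must sum to 1 (got %.12f)", what, sum(p))
  }
  invisible(TRUE)
}
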