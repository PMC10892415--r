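#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in the reported one-decimal
#' prevalence percentages. Base R's `round()` rounds half to even, which turns
#' e.g. 10.95 into 10.9 rather than 11.0; report tables here always carry the
#' half up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the reporting precision
#'   for percentages).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(c(7.75, 13.85), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), digits >= 0)
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# shared input check: x must be a data frame containing `cols`
check_columns <- function(x, cols, what) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", what, class(x)[1]))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", toString(missing)
    ))
  }
  invisible(x)
}

check_scalar_prob <- function(x, name, lower = 0, upper = 1,
                              lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%s, %s%s.",
      name, if (lower_open) "(" else "[", format(lower),
      format(upper), if (upper_open) ")" else "]"
    ))
  }
  invisible(x)
}
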