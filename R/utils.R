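# Shared helpers: rounding convention, argument checks.

#' Round half away from zero
#'
#' Reported percentages use half-up rounding to a fixed number of decimals
#' (so 26.45 -> 26.5), rather than the round-half-even convention of
#' [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(100 * 188 / 712)   # 26.4
#' round_half_up(0.25, 1)           # 0.3
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "mirlink_config_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]; got %s.",
                  name, format(lower), format(upper), format(x)),
          class = "mirlink_config_error")
  }
  if (integer && x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number; got %s.", name, format(x)),
          class = "mirlink_config_error")
  }
  invisible(x)
}

check_range_pair <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2]) {
    abort(sprintf("`%s` must be a non-decreasing pair of numbers.", name),
          class = "mirlink_config_error")
  }
  if (any(x < lower)) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)),
          class = "mirlink_config_error")
  }
  invisible(x)
}

`%+%` <- function(a, b) paste0(a, b)
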