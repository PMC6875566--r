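# Internal helpers shared across modules.

# Classed error constructors so callers can distinguish bad arguments from
# genuine numerical/domain failures.
abort_invalid <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("invalid `%s`: %s", field, msg)
  stop(structure(
    class = c("rmgrowth_invalid_input", "rmgrowth_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_domain <- function(msg) {
  stop(structure(
    class = c("rmgrowth_domain_error", "rmgrowth_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_prob <- function(x, field, allow_na = FALSE) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) abort_invalid(sprintf("must lie in [0, 1], got %s",
                                      paste(x[bad], collapse = ", ")), field)
  if (!allow_na && anyNA(x)) abort_invalid("must not contain missing values", field)
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (1.075 -> 1.08 at two
#' decimals), the convention used throughout for comparing computed
#' quantities against values printed at fixed precision. Base [round()]
#' rounds half to even, which disagrees with printed tables on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(1.075, 2)  # 1.08, where round() gives 1.07
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Truncate toward zero at `digits` decimals (keep the printed digits, drop
# the rest) -- the convention that reproduces the fixture's recruitment
# column.
trunc_digits <- function(x, digits = 2) {
  p <- 10^digits
  trunc(x * p) / p
}
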