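#' Round half away from zero
#'
#' Commercial ("round-half-up") rounding, as used on billing schedules and in
#' published economic tables, in contrast to [base::round()]'s banker's
#' rounding. Halves round away from zero so that `$0.125 -> $0.13` and
#' `-$0.125 -> -$0.13`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(2.5)    # 3, where round(2.5) gives 2
#' round_half_up(30.815, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny bump absorbs binary-representation error just below an exact half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Money helpers (integer cents)
#'
#' Monetary amounts are carried internally as integer cents so that exact
#' published figures survive arithmetic without binary floating-point drift;
#' dollars are materialised only at the boundary. `as_cents()` applies
#' round-half-up at the cent.
#'
#' @param x Dollars (numeric) for `as_cents()`; integer cents for
#'   `cents_to_dollars()`.
#' @return `as_cents()`: numeric vector of whole cents. `cents_to_dollars()`:
#'   dollars with at most two decimals.
#' @examples
#' as_cents(30.815)           # 3082
#' cents_to_dollars(3082)     # 30.82
#' @export
as_cents <- function(x) {
  round_half_up(x * 100)
}

#' @rdname as_cents
#' @export
cents_to_dollars <- function(x) {
  x / 100
}

#' Format a dollar amount the way economic tables print it
#'
#' @param x Dollars.
#' @param digits Decimal places (0 for whole-dollar table cells).
#' @return Character vector with thousands separators, e.g. `"244,419"`.
#' @keywords internal
fmt_money <- function(x, digits = 0) {
  formatC(round_half_up(x, digits),
    format = "f", digits = digits, big.mark = ","
  )
}

#' Format a proportion as a display percentage
#'
#' @param p Proportion in `[0, 1]`.
#' @param digits Decimal places of the percentage (0 or 1 in the reports).
#' @return Character vector such as `"86%"` or `"21.7%"`.
#' @keywords internal
fmt_pct <- function(p, digits = 0) {
  paste0(formatC(round_half_up(100 * p, digits), format = "f", digits = digits), "%")
}
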