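# Headline summary arithmetic with the reporting conventions used in the
# results tables: rounding is half-away-from-zero and applied only at
# formatting, never inside intermediate computation.

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percent decline between two rates
#'
#' `100 * (rate_start - rate_end) / rate_start`, rounded to the nearest
#' integer percent (half away from zero).
#'
#' @param rate_start,rate_end rates on a common scale; `rate_start > 0`.
#' @param digits rounding digits (default 0).
#' @return the rounded percent decline.
#' @examples
#' percent_decline(4.9, 1.4)  # 71
#' percent_decline(170, 53)   # 69
#' @export
percent_decline <- function(rate_start, rate_end, digits = 0) {
  if (any(rate_start <= 0)) stop("`rate_start` must be positive")
  round_half_up(100 * (rate_start - rate_end) / rate_start, digits)
}

#' Fold change between two quantities
#'
#' `a / b`, rounded to one decimal by default.
#'
#' @param a numerator.
#' @param b denominator, nonzero.
#' @param digits rounding digits (default 1).
#' @return the rounded ratio.
#' @examples
#' fold_change(170, 53)         # 3.2
#' fold_change(273000, 118000)  # 2.3
#' @export
fold_change <- function(a, b, digits = 1) {
  if (any(b == 0)) stop("`b` must be nonzero")
  round_half_up(a / b, digits)
}

#' Share of a total, as a percent
#'
#' `100 * numerator / denominator`, formatted to 2 decimals below 1% and 1
#' decimal otherwise.
#'
#' @param numerator count, `0 <= numerator <= denominator`.
#' @param denominator positive count.
#' @return the rounded percent share.
#' @examples
#' share(288813, 92400000)  # 0.31
#' share(212116, 288813)    # 73.4
#' @export
share <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("`denominator` must be positive")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("`numerator` must lie in [0, denominator]")
  }
  pct <- 100 * numerator / denominator
  ifelse(pct < 1, round_half_up(pct, 2), round_half_up(pct, 1))
}
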