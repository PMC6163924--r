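# Internal helpers: classed conditions and display rounding.

# All package errors carry a subclass so callers can distinguish, e.g.,
# a zero-denominator index from a mis-specified grid.
stop_ev <- function(subclass, message, ...) {
  stop(structure(
    class = c(subclass, "earlyvigor_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Round half away from zero
#'
#' Display rounding used throughout the summary stage. Unlike [round()],
#' which rounds half to even, values exactly halfway are rounded away from
#' zero (0.605 -> 0.61 at two decimals). A small guard absorbs binary
#' representation error so that printed-looking decimals behave as written.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Coefficient of variation with sample (n-1) standard deviation.
cv_sample <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / mean(x)
}

# hue-window membership, wrap-around across 0 degrees permitted
in_hue_window <- function(h, hue_min, hue_max) {
  if (hue_min <= hue_max) h >= hue_min & h <= hue_max else h >= hue_min | h <= hue_max
}
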