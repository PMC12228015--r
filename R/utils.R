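# Shared numeric helpers: display rounding and percentage formatting
# conventions used by every reporting surface of the package.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published epidemiological tables
#' almost always round half away from zero (2.145 -> 2.15, 36.5 -> 37).
#' All display rounding in this package goes through this helper so that
#' printed figures match that convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(2.145, 2)
#' round_half_away(c(36.384, 29.1, 43.82))
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulps so values that are exactly .5 after decimal scaling
  # (up to binary representation) round away from zero rather than down
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a percentage string
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @param digits Decimal places after conversion to percent (default 2).
#' @return Character vector like `"3.64"` (no percent sign appended).
#' @export
format_pct <- function(x, digits = 2) {
  formatC(round_half_away(100 * x, digits), format = "f", digits = digits)
}

# Two-sided normal quantile for a confidence level, e.g. 1.959964 at 0.95.
z_for_level <- function(level) stats::qnorm(1 - (1 - level) / 2)

stop_if_not_proportion <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a proportion in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L ||
      !is.finite(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  invisible(level)
}

stop_if_not_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}
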