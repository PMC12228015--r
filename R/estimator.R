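# Core estimator: FASD prevalence as the product of PAE prevalence and the
# FASD-given-PAE risk, with Monte Carlo percentile confidence intervals and
# burden conversions.

#' Point prevalence of FASD
#'
#' The prevalence model is a quotient: population FASD prevalence equals the
#' PAE prevalence divided by the number of exposed pregnancies per case.
#' Writing the reciprocal as a risk, it is the product
#' `p_pae * risk`, which this function returns exactly.
#'
#' @param p_pae Prevalence of prenatal alcohol exposure, in `[0, 1]`.
#' @param risk Risk of FASD given PAE, in `[0, 1]`.
#' @return `p_pae * risk`.
#' @examples
#' point_prevalence(0.48, 0.0758)   # 0.036384, prints as 3.64%
#' @export
point_prevalence <- function(p_pae, risk) {
  stop_if_not_proportion(p_pae, "p_pae")
  stop_if_not_proportion(risk, "risk")
  p_pae * risk
}

#' Monte Carlo prevalence estimate with percentile confidence interval
#'
#' Draws `n_draws` independent (PAE, risk) pairs — the PAE block first, the
#' risk block second, from a single generator seeded once per call, so runs
#' are bit-reproducible — forms the elementwise product, and takes the
#' `(1 - level)/2` and `1 - (1 - level)/2` empirical percentiles (type-7,
#' linear interpolation) as the confidence interval. The point estimate is
#' set analytically to `mean(pae) * mean_risk`, which removes simulation
#' noise from the headline number and coincides with the Monte Carlo mean
#' in expectation because the two inputs are independent.
#'
#' @param pae PAE distribution: a [beta_spec()], a [summary_proportion()]
#'   (fitted via [fit_beta_from_summary()], or treated as a point mass if
#'   its interval has zero width), or a bare proportion (point mass).
#' @param risk A [risk_model()][make_risk_model].
#' @param n_draws Number of Monte Carlo draws, at least 10^4 (percentile
#'   estimates are unstable below that). Default 10^6.
#' @param seed Integer seed; required, so no run depends on ambient RNG
#'   state. The caller's RNG state is left untouched.
#' @param level Confidence level (default 0.95).
#' @param label Free-text label attached to the estimate.
#' @param range Optional `c(lo, hi)` PAE study range; when supplied the
#'   estimate carries [prevalence_range()] evaluated at the headline risk
#'   rounded to 4 decimals (0.0769 for one-in-13).
#' @param keep_draws Keep the product draws in the result (default FALSE;
#'   at 10^6 draws this is 8 MB).
#' @return An object of class `prevalence_estimate`: fields `point`,
#'   `ci_low`, `ci_high`, `range`, `level`, `n_draws`, `seed`, `per_1000`
#'   (integer triple, see [per_thousand()]), `label`, and `inputs` (the
#'   `pae` and `risk` models, retained so comparisons can re-run them).
#' @examples
#' est <- mc_prevalence(beta_spec(50.49, 54.69),
#'                      make_risk_model(13, c(0.0725, 0.0790)),
#'                      n_draws = 1e5, seed = 1)
#' est
#' @export
mc_prevalence <- function(pae, risk, n_draws = 1e6, seed, level = 0.95,
                          label = "", range = NULL, keep_draws = FALSE) {
  stopifnot(inherits(risk, "risk_model"))
  stop_if_not_count(n_draws, "n_draws", min = 1)
  if (n_draws < 1e4) {
    stop("`n_draws` must be at least 10^4 for stable percentile estimates",
         call. = FALSE)
  }
  if (missing(seed)) stop("`seed` must be supplied explicitly", call. = FALSE)
  stop_if_not_count(seed, "seed")
  stop_if_not_level(level)

  draws <- withr::with_seed(as.integer(seed), {
    p <- sample_pae(pae, n_draws)
    r <- sample_risk(risk, n_draws)
    p * r
  })
  a2 <- (1 - level) / 2
  ci <- unname(stats::quantile(draws, c(a2, 1 - a2), type = 7, names = FALSE))
  point <- point_prevalence(pae_mean(pae), risk$mean_risk)
  if (point < ci[1] || point > ci[2]) {
    warning("analytic point estimate falls outside the Monte Carlo ",
            "percentile interval; inputs are likely inconsistent",
            call. = FALSE)
  }
  est <- structure(
    list(point = point, ci_low = ci[1], ci_high = ci[2],
         range = if (!is.null(range)) {
           # range convention: the headline risk rounded to 4 decimals
           prevalence_range(range[1], range[2],
                            round_half_away(risk$headline, 4))
         },
         level = level, n_draws = n_draws, seed = as.integer(seed),
         per_1000 = NULL, label = as.character(label),
         inputs = list(pae = pae, risk = risk),
         draws = if (keep_draws) draws),
    class = "prevalence_estimate"
  )
  est$per_1000 <- per_thousand(est)
  est
}

#' Deterministic prevalence range from a PAE study range
#'
#' Converts the across-study range of PAE prevalence into a range of FASD
#' prevalence by multiplying both endpoints by a fixed headline risk. The
#' default risk is the rounded reciprocal of one-in-13, 0.0769, the
#' convention that reproduces published range endpoints exactly; pass the
#' working mean risk (0.0758) for the alternative convention.
#'
#' @param pae_lo,pae_hi PAE range endpoints, `pae_lo <= pae_hi`.
#' @param headline_risk Risk multiplier (default 0.0769).
#' @return Numeric `c(lo, hi)`.
#' @examples
#' prevalence_range(0.142, 0.76)   # c(0.0109198, 0.0584440) -> 1.09%, 5.84%
#' @export
prevalence_range <- function(pae_lo, pae_hi, headline_risk = 0.0769) {
  stop_if_not_proportion(pae_lo, "pae_lo")
  stop_if_not_proportion(pae_hi, "pae_hi")
  stop_if_not_proportion(headline_risk, "headline_risk")
  if (pae_lo > pae_hi) stop("`pae_lo` must not exceed `pae_hi`", call. = FALSE)
  c(pae_lo, pae_hi) * headline_risk
}

#' Cases per 1000 children
#'
#' Converts a prevalence estimate to the integer per-1000 scale used in
#' burden statements: each proportion times 1000, rounded half away from
#' zero.
#'
#' @param est A `prevalence_estimate`.
#' @return Integer vector `c(rate, ci_low, ci_high)`.
#' @examples
#' # point 0.036384 with CI (0.0291, 0.0441) -> 36 (29, 44) per 1000
#' @export
per_thousand <- function(est) {
  stopifnot(inherits(est, "prevalence_estimate"))
  out <- round_half_away(1000 * c(est$point, est$ci_low, est$ci_high))
  stats::setNames(as.integer(out), c("rate", "ci_low", "ci_high"))
}

#' Affected births for a user-supplied births denominator
#'
#' @param prevalence FASD prevalence, a proportion.
#' @param births Annual births count (>= 0).
#' @return `round(prevalence * births)` (half away from zero).
#' @examples
#' affected_births(0.05, 1000)
#' @export
affected_births <- function(prevalence, births) {
  stop_if_not_proportion(prevalence, "prevalence")
  if (!is.numeric(births) || length(births) != 1L || !is.finite(births) ||
      births < 0) {
    stop("`births` must be a single non-negative number", call. = FALSE)
  }
  round_half_away(prevalence * births)
}

#' Render a prevalence estimate in report style
#'
#' @param est A `prevalence_estimate`.
#' @param digits Decimal places on the percentage scale (default 2).
#' @return A string like
#'   `"3.64% (95% CI 2.91%, 4.41%; range: 1.09%, 5.84%)"`.
#' @export
format_estimate <- function(est, digits = 2) {
  stopifnot(inherits(est, "prevalence_estimate"))
  txt <- sprintf("%s%% (%d%% CI %s%%, %s%%",
                 format_pct(est$point, digits), round(100 * est$level),
                 format_pct(est$ci_low, digits),
                 format_pct(est$ci_high, digits))
  if (!is.null(est$range)) {
    txt <- sprintf("%s; range: %s%%, %s%%", txt,
                   format_pct(est$range[1], digits),
                   format_pct(est$range[2], digits))
  }
  paste0(txt, ")")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  if (nzchar(x$label)) cat(x$label, "\n")
  cat("FASD prevalence:", format_estimate(x), "\n")
  cat(sprintf("  = %d (%d%% CI %d, %d) cases per 1000 children\n",
              x$per_1000[["rate"]], round(100 * x$level),
              x$per_1000[["ci_low"]], x$per_1000[["ci_high"]]))
  cat(sprintf("  [%s draws, seed %d]\n",
              format(x$n_draws, big.mark = ",", scientific = FALSE), x$seed))
  invisible(x)
}

#' Flatten a prevalence estimate to a one-row data frame
#'
#' @param x A `prevalence_estimate`.
#' @param row.names,optional,... Ignored; present for S3 compatibility.
#' @return One row with label, point, CI, range, per-1000 triple, draw
#'   count and seed — the record serialised to CSV/JSON by [cmd_estimate()].
#' @export
as.data.frame.prevalence_estimate <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(
    label = x$label, point = x$point,
    ci_low = x$ci_low, ci_high = x$ci_high, level = x$level,
    range_low = if (is.null(x$range)) NA_real_ else x$range[1],
    range_high = if (is.null(x$range)) NA_real_ else x$range[2],
    per_1000 = x$per_1000[["rate"]],
    per_1000_low = x$per_1000[["ci_low"]],
    per_1000_high = x$per_1000[["ci_high"]],
    pct = format_pct(x$point), pct_ci_low = format_pct(x$ci_low),
    pct_ci_high = format_pct(x$ci_high),
    n_draws = x$n_draws, seed = x$seed,
    stringsAsFactors = FALSE
  )
}
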