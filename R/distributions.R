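# Distributional inputs to the prevalence model: summary proportions as
# published (mean + CI), beta distributions fitted to them by moment
# matching, and the risk-of-FASD-given-PAE model.

#' Summary proportion (mean with confidence interval)
#'
#' Container for a proportion the way epidemiological papers report it:
#' a point value with a two-sided confidence interval, optionally with the
#' pooled sample size behind it. This is the exchange format between the
#' published evidence (prenatal alcohol exposure prevalence, FASD risk) and
#' the distribution-fitting step.
#'
#' @param mean Point estimate, a proportion in `[0, 1]`.
#' @param ci_low,ci_high Interval bounds, proportions with
#'   `ci_low <= mean <= ci_high`.
#' @param level Confidence level of the interval, strictly in (0, 1).
#'   Default 0.95.
#' @param label Free-text description of what the proportion measures.
#' @param n Optional pooled sample size behind the estimate.
#' @return An object of class `summary_proportion`.
#' @examples
#' summary_proportion(0.48, 0.38, 0.57, label = "PAE prevalence, Australia")
#' @export
summary_proportion <- function(mean, ci_low, ci_high, level = 0.95,
                               label = "", n = NULL) {
  stop_if_not_proportion(mean, "mean")
  stop_if_not_proportion(ci_low, "ci_low")
  stop_if_not_proportion(ci_high, "ci_high")
  stop_if_not_level(level)
  if (ci_low > mean || mean > ci_high) {
    stop("interval must bracket the mean: ci_low <= mean <= ci_high",
         call. = FALSE)
  }
  if (!is.null(n)) stop_if_not_count(n, "n", min = 1)
  structure(
    list(mean = mean, ci_low = ci_low, ci_high = ci_high,
         level = level, label = as.character(label), n = n),
    class = "summary_proportion"
  )
}

#' @export
print.summary_proportion <- function(x, ...) {
  cat(sprintf("%s%% (%d%% CI %s%%, %s%%)%s\n",
              format_pct(x$mean), round(100 * x$level),
              format_pct(x$ci_low), format_pct(x$ci_high),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Beta distribution specification
#'
#' Shape parameters of a beta distribution on `[0, 1]`, used to model
#' uncertainty in a prevalence proportion.
#'
#' @param alpha,beta Positive shape parameters.
#' @return An object of class `beta_spec` with fields `alpha` and `beta`.
#' @examples
#' beta_spec(50.49, 54.69)
#' @export
beta_spec <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || !is.finite(alpha) || !is.finite(beta) ||
      alpha <= 0 || beta <= 0) {
    stop("`alpha` and `beta` must be single positive numbers", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "beta_spec")
}

#' @export
print.beta_spec <- function(x, ...) {
  cat(sprintf("beta(alpha = %.4g, beta = %.4g), mean %.4f, sd %.4g\n",
              x$alpha, x$beta, beta_mean(x), beta_sd(x)))
  invisible(x)
}

#' Analytic mean and standard deviation of a beta specification
#'
#' @param b A [beta_spec()].
#' @return `beta_mean`: `alpha / (alpha + beta)`. `beta_sd`: the closed-form
#'   standard deviation.
#' @export
beta_mean <- function(b) b$alpha / (b$alpha + b$beta)

#' @rdname beta_mean
#' @export
beta_sd <- function(b) {
  s <- b$alpha + b$beta
  sqrt(b$alpha * b$beta / (s^2 * (s + 1)))
}

#' Fit a beta distribution to a reported mean and confidence interval
#'
#' Moment matching: the interval half-width divided by the two-sided normal
#' quantile for the interval's level is taken as the standard deviation,
#' `sd = (ci_high - ci_low) / (2 z)`, and the shapes solve the beta moment
#' equations `alpha = m nu`, `beta = (1 - m) nu` with
#' `nu = m (1 - m) / sd^2 - 1`. Applied to the pooled Australian PAE
#' prevalence of 48% (95% CI 38%, 57%) this yields shapes within 0.1 of
#' (50.49, 54.69), the parameterisation used for the headline estimate.
#'
#' @param s A [summary_proportion()] with a non-degenerate interval.
#' @return A [beta_spec()] whose analytic mean equals `s$mean` and whose
#'   standard deviation equals the normal-theory value implied by the CI.
#' @examples
#' fit_beta_from_summary(summary_proportion(0.48, 0.38, 0.57))
#' @seealso [beta_summary()] for the inverse operation.
#' @export
fit_beta_from_summary <- function(s) {
  stopifnot(inherits(s, "summary_proportion"))
  if (s$ci_high <= s$ci_low) {
    stop("zero-variance input: ci_high must exceed ci_low to fit a beta",
         call. = FALSE)
  }
  if (s$mean <= 0 || s$mean >= 1) {
    stop("mean must lie strictly inside (0, 1) to fit a beta", call. = FALSE)
  }
  sdev <- (s$ci_high - s$ci_low) / (2 * z_for_level(s$level))
  v <- sdev^2
  if (v >= s$mean * (1 - s$mean)) {
    stop("infeasible beta: implied variance >= mean * (1 - mean)",
         call. = FALSE)
  }
  nu <- s$mean * (1 - s$mean) / v - 1
  beta_spec(s$mean * nu, (1 - s$mean) * nu)
}

#' Summarise a beta specification as mean and quantile interval
#'
#' Inverse of [fit_beta_from_summary()]: the mean is `alpha / (alpha + beta)`
#' and the interval bounds are the `(1 - level)/2` and `1 - (1 - level)/2`
#' quantiles of the beta distribution.
#'
#' @param b A [beta_spec()].
#' @param level Confidence level (default 0.95).
#' @param label Passed through to the result.
#' @return A [summary_proportion()].
#' @export
beta_summary <- function(b, level = 0.95, label = "") {
  stopifnot(inherits(b, "beta_spec"))
  stop_if_not_level(level)
  a2 <- (1 - level) / 2
  summary_proportion(
    mean = beta_mean(b),
    ci_low = stats::qbeta(a2, b$alpha, b$beta),
    ci_high = stats::qbeta(1 - a2, b$alpha, b$beta),
    level = level, label = label
  )
}

#' Risk of FASD among alcohol-exposed pregnancies
#'
#' Builds the risk side of the prevalence product from the form in which it
#' is published: "one case of FASD per `n_per_case` exposed pregnancies",
#' together with a confidence interval for the risk proportion. Two risk
#' values are carried deliberately:
#'
#' * `headline`: `1 / n_per_case` — the quotable reciprocal (one in 13 is
#'   7.69%), used by default for the deterministic range conversion
#'   ([prevalence_range()]).
#' * `mean_risk`: the working mean used for point estimates and as the mean
#'   of the Monte Carlo risk distribution. By default it is the interval
#'   midpoint rounded half away from zero to 4 decimals (0.0758 for the
#'   published interval 7.25%-7.90%), which is the value consistent with the
#'   published point estimates; supply `mean_risk` explicitly to override,
#'   e.g. with an observed pooled proportion.
#'
#' The Monte Carlo distribution `mc_spec` is a beta moment-matched to
#' (`mean_risk`, interval) via [fit_beta_from_summary()]. If the interval is
#' degenerate (zero width) the risk is treated as a point mass and
#' `mc_spec` is `NULL`. Setting `mc = "binomial"` instead samples the risk
#' as `rbinom(n, pooled_n, mean_risk) / pooled_n`, the interval implied by a
#' single pooled binomial; it is provided for comparison and is
#' substantially narrower than published risk intervals that carry
#' between-study heterogeneity.
#'
#' @param n_per_case Exposed pregnancies per FASD case (> 1).
#' @param interval Numeric `c(lo, hi)` risk interval at `level`.
#' @param pooled_n Optional pooled sample size behind the interval
#'   (required when `mc = "binomial"`).
#' @param mean_risk Optional explicit working mean risk.
#' @param level Confidence level of `interval` (default 0.95).
#' @param mc Monte Carlo model for the risk: `"beta"` (default) or
#'   `"binomial"`.
#' @return An object of class `risk_model` with fields `n_per_case`,
#'   `headline`, `mean_risk`, `interval`, `level`, `pooled_n`, `mc`,
#'   and `mc_spec`.
#' @examples
#' make_risk_model(13, c(0.0725, 0.0790), pooled_n = 158161)
#' @export
make_risk_model <- function(n_per_case, interval, pooled_n = NULL,
                            mean_risk = NULL, level = 0.95,
                            mc = c("beta", "binomial")) {
  mc <- match.arg(mc)
  if (!is.numeric(n_per_case) || length(n_per_case) != 1L || n_per_case <= 1) {
    stop("`n_per_case` must be a single number > 1", call. = FALSE)
  }
  if (!is.numeric(interval) || length(interval) != 2L ||
      interval[1] > interval[2]) {
    stop("`interval` must be c(lo, hi) with lo <= hi", call. = FALSE)
  }
  stop_if_not_proportion(interval, "interval")
  stop_if_not_level(level)
  if (!is.null(pooled_n)) stop_if_not_count(pooled_n, "pooled_n", min = 1)

  headline <- 1 / n_per_case
  if (headline < interval[1] / 1.2 || headline > interval[2] * 1.2) {
    warning(sprintf(
      "1/n_per_case = %.4g lies outside the interval (%.4g, %.4g) by more ",
      headline, interval[1], interval[2]),
      "than 20% relative; inputs are likely inconsistent", call. = FALSE)
  }
  if (is.null(mean_risk)) {
    mean_risk <- round_half_away(mean(interval), 4)
  }
  stop_if_not_proportion(mean_risk, "mean_risk")
  if (mean_risk < interval[1] || mean_risk > interval[2]) {
    stop("`mean_risk` must lie inside `interval`", call. = FALSE)
  }

  mc_spec <- NULL
  if (interval[2] > interval[1]) {
    mc_spec <- fit_beta_from_summary(summary_proportion(
      mean_risk, interval[1], interval[2], level = level,
      label = "FASD risk given PAE"
    ))
    stopifnot(abs(beta_mean(mc_spec) - mean_risk) < 1e-6)
  }
  if (mc == "binomial" && is.null(pooled_n)) {
    stop("`pooled_n` is required when mc = \"binomial\"", call. = FALSE)
  }
  structure(
    list(n_per_case = n_per_case, headline = headline, mean_risk = mean_risk,
         interval = interval, level = level, pooled_n = pooled_n,
         mc = mc, mc_spec = mc_spec),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf(
    "FASD risk given PAE: 1 in %.4g exposed pregnancies = %s%%\n",
    x$n_per_case, format_pct(x$headline)))
  cat(sprintf("  working mean %s%%, %d%% CI (%s%%, %s%%), MC model: %s\n",
              format_pct(x$mean_risk), round(100 * x$level),
              format_pct(x$interval[1]), format_pct(x$interval[2]),
              if (is.null(x$mc_spec) && x$mc == "beta") "point mass" else x$mc))
  invisible(x)
}

#' Draw risk values from a risk model's Monte Carlo specification
#'
#' Beta draws from `mc_spec`, pooled-binomial draws when the model was
#' built with `mc = "binomial"`, or a constant for a degenerate interval.
#'
#' @param risk A `risk_model`.
#' @param n Number of draws.
#' @return Numeric vector of `n` risk proportions.
#' @export
sample_risk <- function(risk, n) {
  if (risk$mc == "binomial") {
    return(stats::rbinom(n, risk$pooled_n, risk$mean_risk) / risk$pooled_n)
  }
  if (is.null(risk$mc_spec)) return(rep.int(risk$mean_risk, n))
  stats::rbeta(n, risk$mc_spec$alpha, risk$mc_spec$beta)
}

# Draw n values from a PAE model: a beta_spec, a point-mass proportion, or
# a zero-width summary_proportion (treated as a point mass).
sample_pae <- function(pae, n) {
  if (inherits(pae, "beta_spec")) return(stats::rbeta(n, pae$alpha, pae$beta))
  if (inherits(pae, "summary_proportion")) {
    if (pae$ci_high > pae$ci_low) {
      b <- fit_beta_from_summary(pae)
      return(stats::rbeta(n, b$alpha, b$beta))
    }
    return(rep.int(pae$mean, n))
  }
  stop_if_not_proportion(pae, "pae")
  rep.int(pae, n)
}

# Mean of a PAE model under the same conventions as sample_pae().
pae_mean <- function(pae) {
  if (inherits(pae, "beta_spec")) return(beta_mean(pae))
  if (inherits(pae, "summary_proportion")) return(pae$mean)
  stop_if_not_proportion(pae, "pae")
  pae
}
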