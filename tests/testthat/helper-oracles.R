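# Independent oracles used across the suite. Each deliberately avoids the
# package's own code paths: quadrature instead of Monte Carlo, direct
# binomial tail summation instead of binom.test, closed-form beta moments
# instead of the fitting routine.

# CDF of Z = X * Y for X ~ beta(a1, b1), Y ~ beta(a2, b2), by quadrature:
# P(Z <= z) = int_0^1 F_Y(z / x) f_X(x) dx.
product_beta_cdf <- function(z, a1, b1, a2, b2) {
  stats::integrate(function(x) stats::pbeta(z / x, a2, b2) *
                     stats::dbeta(x, a1, b1),
                   lower = 0, upper = 1,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

# Quantile of the product distribution by root finding on the CDF.
product_beta_quantile <- function(p, a1, b1, a2, b2) {
  stats::uniroot(function(z) product_beta_cdf(z, a1, b1, a2, b2) - p,
                 interval = c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

# Clopper-Pearson bounds by direct enumeration of binomial tail
# probabilities: the lower bound is the p at which P(X >= x | p) equals
# alpha/2, found by root finding on the exact tail sum.
cp_enumerated <- function(x, n, level = 0.95) {
  a2 <- (1 - level) / 2
  upper_tail <- function(p) sum(stats::dbinom(x:n, n, p))
  lower_tail <- function(p) sum(stats::dbinom(0:x, n, p))
  lo <- if (x == 0) 0 else {
    stats::uniroot(function(p) upper_tail(p) - a2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  }
  hi <- if (x == n) 1 else {
    stats::uniroot(function(p) lower_tail(p) - a2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  }
  c(lo, hi)
}

# Closed-form beta moments, written out independently of beta_mean/beta_sd.
moments_of_beta <- function(alpha, beta) {
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  c(mean = m, sd = sqrt(v))
}

# Published fixture values asserted throughout the suite.
fix <- list(
  pae_pooled = c(mean = 0.48, lo = 0.38, hi = 0.57),
  pae_range = c(0.142, 0.76),
  ndshs_2019 = c(mean = 0.297, lo = 0.253, hi = 0.341),
  ndshs_2022 = c(mean = 0.283, lo = 0.212, hi = 0.354),
  risk_interval = c(0.0725, 0.0790),
  risk_mean = 0.0758,
  headline_pct = "7.69"
)
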