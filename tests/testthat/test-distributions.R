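# Beta fitting from published summaries, its inverse, and the risk model.

test_that("summary_proportion enforces ordering and level invariants", {
  s <- summary_proportion(0.48, 0.38, 0.57)
  expect_s3_class(s, "summary_proportion")
  expect_error(summary_proportion(0.3, 0.4, 0.5), "bracket")
  expect_error(summary_proportion(0.5, 0.4, 0.45), "bracket")
  expect_error(summary_proportion(0.5, 0.4, 0.6, level = 1), "level")
  expect_error(summary_proportion(1.2, 0.4, 0.6), "proportion")
})

test_that("moment matching recovers the published PAE beta shapes", {
  b <- fit_beta_from_summary(summary_proportion(0.48, 0.38, 0.57))
  expect_lt(abs(b$alpha - 50.49), 0.5)
  expect_lt(abs(b$beta - 54.69), 0.5)
  # fitted mean is exact; fitted sd equals the normal-theory CI half-width
  expect_equal(beta_mean(b), 0.48, tolerance = 1e-12)
  expect_equal(beta_sd(b), (0.57 - 0.38) / (2 * qnorm(0.975)),
               tolerance = 1e-9)
})

test_that("a symmetric interval about 0.5 forces equal shapes", {
  b <- fit_beta_from_summary(summary_proportion(0.5, 0.4, 0.6))
  expect_equal(b$alpha, b$beta, tolerance = 1e-6)
})

test_that("NDSHS summaries round-trip through the closed-form moments", {
  # frozen from the moment-matching identities computed ahead of the build
  cases <- list(
    list(s = fix$ndshs_2019, shapes = c(122.7466, 290.5416)),
    list(s = fix$ndshs_2022, shapes = c(43.47642, 110.15049))
  )
  for (cs in cases) {
    b <- fit_beta_from_summary(
      summary_proportion(cs$s[["mean"]], cs$s[["lo"]], cs$s[["hi"]]))
    expect_equal(c(b$alpha, b$beta), cs$shapes, tolerance = 1e-4)
    m <- moments_of_beta(b$alpha, b$beta)
    expect_lt(abs(m[["mean"]] - cs$s[["mean"]]), 1e-3)
    target_sd <- (cs$s[["hi"]] - cs$s[["lo"]]) / (2 * qnorm(0.975))
    expect_lt(abs(m[["sd"]] / target_sd - 1), 0.02)
  }
})

test_that("degenerate and infeasible summaries are rejected", {
  expect_error(fit_beta_from_summary(summary_proportion(0.5, 0.5, 0.5)),
               "zero-variance")
  # CI so wide the implied variance exceeds m(1 - m)
  expect_error(fit_beta_from_summary(summary_proportion(0.02, 0, 0.9)),
               "infeasible")
})

test_that("beta_summary inverts the fit and matches known quantiles", {
  s <- beta_summary(beta_spec(50.49, 54.69))
  expect_equal(format_pct(s$mean, 0), "48")
  u <- beta_summary(beta_spec(1, 1))
  expect_equal(u$mean, 0.5)
  expect_equal(c(u$ci_low, u$ci_high), c(0.025, 0.975), tolerance = 1e-12)
})

test_that("beta_summary quantiles agree with direct-sampling quantiles", {
  specs <- list(beta_spec(50.49, 54.69), beta_spec(122.7466, 290.5416),
                beta_spec(43.47642, 110.15049), beta_spec(1931.2, 23545.8))
  withr::with_seed(424242, {
    for (b in specs) {
      s <- beta_summary(b)
      emp <- quantile(rbeta(1e6, b$alpha, b$beta), c(0.025, 0.975))
      expect_lt(max(abs(c(s$ci_low, s$ci_high) - emp)), 0.002)
    }
  })
})

test_that("fit and summary round-trip across a wide shape grid", {
  # the CI-width <-> sd identification assumes a near-normal quantile
  # interval; it holds to 2% once both shapes are ~10 or larger
  for (alpha in c(10, 50, 800, 1e5)) {
    for (beta in c(12, 60, 2.4e4)) {
      b0 <- beta_spec(alpha, beta)
      b1 <- fit_beta_from_summary(beta_summary(b0))
      expect_lt(abs(beta_mean(b1) - beta_mean(b0)), 1e-3)
      expect_lt(abs(beta_sd(b1) / beta_sd(b0) - 1), 0.02)
    }
  }
})

test_that("round-trip degrades for strongly skewed small-shape betas", {
  # quantile intervals of skewed betas are wider than +/- z sd, so the
  # recovered sd is biased low -- a documented limit of moment matching
  b1 <- fit_beta_from_summary(beta_summary(beta_spec(2, 2)))
  expect_gt(abs(beta_sd(b1) / beta_sd(beta_spec(2, 2)) - 1), 0.02)
})

test_that("mirrored summaries yield swapped shapes", {
  s <- summary_proportion(0.297, 0.253, 0.341)
  sm <- summary_proportion(1 - 0.297, 1 - 0.341, 1 - 0.253)
  b <- fit_beta_from_summary(s)
  bm <- fit_beta_from_summary(sm)
  expect_equal(bm$alpha, b$beta, tolerance = 1e-9)
  expect_equal(bm$beta, b$alpha, tolerance = 1e-9)
})

test_that("risk model carries both the headline and the working mean", {
  r <- make_risk_model(13, fix$risk_interval, pooled_n = 158161)
  expect_equal(format_pct(r$headline), fix$headline_pct)
  expect_equal(r$mean_risk, fix$risk_mean)
  # MC beta: mean pinned to the working mean, sd from the interval width
  expect_lt(abs(beta_mean(r$mc_spec) - r$mean_risk), 1e-6)
  expect_equal(beta_sd(r$mc_spec),
               (0.0790 - 0.0725) / (2 * qnorm(0.975)), tolerance = 1e-6)
  # shapes frozen from moment matching computed ahead of the build
  expect_equal(r$mc_spec$alpha, 1931.153, tolerance = 1e-3)
  expect_equal(r$mc_spec$beta, 23545.805, tolerance = 1e-3)
})

test_that("reciprocal identity and degenerate risk intervals work", {
  r <- make_risk_model(2, c(0.49, 0.51))
  expect_equal(r$headline, 0.5)
  expect_equal(r$mean_risk, 0.5)
  rp <- make_risk_model(13, c(0.0769, 0.0769), mean_risk = 0.0769)
  expect_null(rp$mc_spec)
  expect_identical(sample_risk(rp, 5), rep(0.0769, 5))
})

test_that("an interval inconsistent with 1/n_per_case warns", {
  expect_warning(make_risk_model(13, c(0.20, 0.30), mean_risk = 0.25),
                 "inconsistent")
  expect_silent(make_risk_model(13, fix$risk_interval))
})

test_that("binomial risk sampling needs pooled_n and matches its moments", {
  expect_error(make_risk_model(13, fix$risk_interval, mc = "binomial"),
               "pooled_n")
  r <- make_risk_model(13, fix$risk_interval, pooled_n = 158161,
                       mc = "binomial")
  d <- withr::with_seed(11, sample_risk(r, 2e5))
  expect_lt(abs(mean(d) - r$mean_risk), 1e-3)
  # pooled-binomial spread, sqrt(p(1-p)/n): far narrower than the
  # published interval implies -- the reason the beta model is the default
  expect_lt(abs(sd(d) / sqrt(0.0758 * (1 - 0.0758) / 158161) - 1), 0.01)
  expect_lt(sd(d), 0.5 * beta_sd(make_risk_model(13, fix$risk_interval)$mc_spec))
})
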