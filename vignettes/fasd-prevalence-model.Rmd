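---
title: "Estimating FASD prevalence from indirect evidence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating FASD prevalence from indirect evidence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasdprev)
```

## The problem

Fetal alcohol spectrum disorder (FASD) is a lifelong neurodevelopmental
condition caused by prenatal alcohol exposure (PAE). The gold standard for
measuring its population prevalence — active case ascertainment, in which a
representative sample of children is screened and diagnosed by a
multidisciplinary clinical team — is expensive, slow, and ethically
delicate. Where no such study exists, prevalence can still be estimated
indirectly by combining two published quantities:

* the prevalence of PAE in the population of interest, available from
  meta-analyses of birth cohorts and from household surveys; and
* the risk that an alcohol-exposed pregnancy results in a child with FASD,
  available from international meta-analysis as "one case per $N$ exposed
  pregnancies".

The estimator is the quotient

$$
P_{\mathrm{FASD}} \;=\; \frac{P_{\mathrm{PAE}}}{N}
\;=\; P_{\mathrm{PAE}} \times r,
\qquad r = 1/N ,
$$

where $r$ is the risk of FASD given PAE. `fasdprev` implements this
estimator with full uncertainty propagation, sensitivity scenarios, burden
conversions, and a synthetic-data harness that checks the statistical
calibration of the whole pipeline.

## From printed summaries to distributions

Every input arrives as a printed summary — a mean with a 95% confidence
interval — rather than as microdata. The package represents such a summary
as a `summary_proportion` and converts it to a beta distribution by
**moment matching** (`fit_beta_from_summary()`):

$$
\hat\sigma = \frac{\mathrm{ci}_{hi} - \mathrm{ci}_{lo}}{2\,z_{0.975}},
\qquad
\nu = \frac{m(1-m)}{\hat\sigma^2} - 1,
\qquad
\alpha = m\nu,\; \beta = (1-m)\nu ,
$$

with $z_{0.975} = 1.959964$ kept at full precision so that results are
bit-reproducible. Applied to the pooled Australian PAE prevalence of 48%
(95% CI 38%, 57%) this gives:

```{r}
fit_beta_from_summary(pae_australia_pooled())
```

The identification of the CI half-width with $z\hat\sigma$ assumes the
interval is near-normal. For the concentrated betas that arise from
published prevalence summaries (both shapes well above 10) the
fit-then-summarise round trip recovers the standard deviation to better
than 2%; for strongly skewed small-shape betas (e.g. beta(2, 2)) the
quantile interval is materially wider than $\pm z\sigma$ and the recovered
standard deviation is biased low by several percent. The test suite pins
both behaviours.

Fitting fails loudly on a degenerate interval (zero implied variance) and
on an interval so wide that the implied variance reaches $m(1-m)$, which no
beta distribution can represent.

## The risk model: two risk values, on purpose

The published risk of FASD given PAE is "one in 13 exposed pregnancies",
i.e. a headline risk of $1/13 = 7.69\%$, with a 95% CI of (7.25%, 7.90%)
obtained by the source authors from binomial sampling over their pooled
studies (n = 158,161). These numbers are mutually inconsistent in two
small but consequential ways, and `make_risk_model()` resolves them
explicitly rather than silently:

* **Working mean (`mean_risk`).** The headline 7.69% does not reproduce
  the published point estimates when multiplied by the PAE inputs
  ($0.48 \times 0.0769 = 3.69\%$, not the published 3.64%). The interval
  midpoint rounded to four decimals, 0.0758, reproduces all three
  published point estimates (3.64%, 2.25%, 2.15%) under two-decimal
  display rounding, and is therefore the default working mean used for
  point estimates and as the Monte Carlo mean. The raw midpoint 0.07575
  fails on the third (it prints 2.14%), which pins the rounding step.
* **Headline (`headline`).** The quotable $1/N$ is kept separately and
  drives the deterministic range conversion (below), because the published
  range endpoints are reproduced by the *rounded* headline 0.0769 and not
  by the working mean.

The Monte Carlo distribution for the risk is a beta moment-matched to
(0.0758, 7.25%–7.90%), shapes ≈ (1931, 23546). A single pooled binomial
with n = 158,161 — the literal reading of the source description — implies
an interval roughly 2.5× narrower than the printed one, presumably because
the printed interval carries between-study variation; the pooled-binomial
option is still available (`mc = "binomial"`) for comparison, and the test
suite demonstrates the width discrepancy.

```{r}
fasd_risk_per_exposed()
```

## Monte Carlo propagation

`mc_prevalence()` draws $10^6$ independent (PAE, risk) pairs — the PAE
block first and the risk block second from one generator seeded once per
call, so identical inputs and seed give bit-identical output — multiplies
them elementwise, and takes the empirical 2.5th and 97.5th percentiles
(type-7, linear interpolation) as the 95% interval. The point estimate is
set analytically to the product of the input means: this removes
simulation noise from the headline number and agrees with the Monte Carlo
mean in expectation because the inputs are independent.

```{r}
est <- mc_prevalence(fit_beta_from_summary(pae_australia_pooled()),
                     fasd_risk_per_exposed(),
                     n_draws = 1e6, seed = 1,
                     label = "Australia pooled birth cohorts",
                     range = attr(pae_australia_pooled(), "range"))
est
```

A deterministic cross-check is built into the tests: the CDF of the
product of two independent betas is computed by quadrature,
$P(XY \le z) = \int_0^1 F_Y(z/x)\, f_X(x)\, dx$, inverted by root finding,
and required to agree with the Monte Carlo percentiles to within
$2\times10^{-4}$. Percentile bounds at $10^6$ draws are stable across
seeds to within $3\times10^{-4}$, so the draw count — chosen to match the
published analysis — is comfortably past convergence for two-decimal
reporting. Draws below $10^4$ are refused outright.

Two conversions accompany the estimate. The **range** multiplies the
across-study PAE range (14.2%–76%) by the rounded headline risk 0.0769,
giving 1.09%–5.84%; this is a deterministic what-if over study settings,
not a confidence statement. The **burden** conversions give cases per 1000
children (rounded half away from zero: 36 (29, 44) for the headline run)
and, when the user supplies a national births denominator, affected births
per year. No births denominator ships with the package, as the underlying
count is not part of the published inputs.

All display rounding is half-away-from-zero, which is what published
tables use; base R's round-half-even would print 2.145 as 2.14 and break
agreement with the published sensitivity estimate.

## Scenarios and comparison

A `scenario` pairs one PAE summary with a risk model; the built-in set
(`default_scenarios()`, also shipped as
`inst/extdata/scenarios.yaml`) carries the pooled birth-cohort estimate
and the two National Drug Strategy Household Survey (NDSHS) waves:

```{r}
ests <- run_scenarios(default_scenarios(), n_draws = 1e5, seed = 42)
for (e in ests) print(e)
```

`compare_scenarios()` offers the informal CI-overlap verdict used in
descriptive epidemiology (the default, and deliberately labelled as such
in its output record: overlap checks are conservative, since intervals
can overlap while a formal test on the difference rejects) and a
`mc_difference` method that re-runs both scenarios on paired fresh draws
— sharing the risk draws when the risk model is common to both, as that
uncertainty is perfectly correlated across scenarios — and reports
$P(a > b)$ with a percentile interval for the difference.

## What the synthetic-data harness does and does not show

`simulate_cohorts()` generates the kind of evidence base the published
inputs summarise: $k = 16$ birth cohorts of 5,000–20,000 pregnancies
(uniform), each cohort's true PAE prevalence drawn from the fitted beta —
the simplest heterogeneity structure consistent with using a beta for the
pooled prevalence — with binomial exposure within cohort and binomial FASD
outcomes among the exposed at a common true risk (0.0769 by default). The
defaults mirror the scale of the published evidence base (16 cohorts;
pooled exposed counts of order $10^5$) and are deliberately not tunable
study conditions: they are what the harness means by "data like the
published inputs".

`pool_cohorts()` aggregates counts and returns exact Clopper–Pearson
intervals by default. For the **coverage experiment** that default would
be wrong in an instructive way: with real between-cohort heterogeneity in
the data, an exact interval on the pooled counts ignores the cohort-level
variance entirely and the full pipeline covers the true prevalence in
only ~55% of replicates rather than the nominal 95%. A published
meta-analytic interval — like the wide 38%–57% interval behind the pooled
PAE estimate, whose implied standard deviation (~0.05 on a pooled n in
the hundreds of thousands) is clearly heterogeneity-driven — absorbs that
variance. `coverage_experiment()` therefore pools the PAE summary with a
t-interval on cohort-level prevalences (`pae_interval = "cohort"`), the
count-based analogue of a random-effects summary; the risk keeps the
exact interval because the generator holds risk constant across cohorts.
Under that convention the measured coverage at 500 replicates of the full
pipeline (simulate → pool → refit beta → Monte Carlo at $10^5$ draws)
falls in the 0.93–1.00 band around nominal 0.95.

What passing these checks shows: the interval machinery is calibrated when
the data really are beta-heterogeneous binomial cohorts and the pooled
summary reflects between-cohort variance. What it does not show: anything
about self-report bias, under-reporting, cohort selection, or secular
trends in the real evidence base — the generator has no mechanism for any
of them, and those biases would shift real estimates in ways no coverage
experiment on this structure can detect.

## Numerical and design choices

* Percentiles: type-7 (linear interpolation). Immaterial at $10^6$ draws,
  pinned for reproducibility.
* RNG contract: one generator, seeded once per call, PAE block before risk
  block; the caller's RNG state is preserved. `run_scenarios()` derives
  per-scenario seeds as `seed + index - 1`.
* Degenerate inputs: zero-width PAE or risk intervals are treated as point
  masses, and a zero-variance run collapses the interval onto the point —
  used by the tests as a boundary case.
* The analytic point estimate can in principle fall outside the percentile
  interval if a caller supplies mutually inconsistent inputs; this is
  flagged with a warning rather than silently accepted.
* `affected_births()` deliberately has no default denominator; published
  affected-birth counts depend on a national births figure that is not
  part of the package's inputs.

## Problem sizes

The shipped tests run the headline analysis at the published $10^6$ draws,
scenario sensitivity runs at $10^6$, the coverage experiment at 500
replicates × $10^5$ draws, and property grids at $2\times10^4$–$5\times10^4$
draws — sizes chosen so the full suite completes in well under a minute of
simulation time while keeping every quantile assertion far inside its
tolerance.

## Known limitations

* The indirect estimator inherits every bias of its inputs; in particular
  self-reported PAE is likely understated, so estimates are best read as
  lower bounds.
* Moment matching assumes near-normal published intervals (see above).
* The CI-overlap comparison is conservative; use `mc_difference` when the
  decision matters.
* The synthetic generator models heterogeneity in PAE only; the true risk
  is held common across cohorts.
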