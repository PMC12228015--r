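# Built-in evidence fixtures: the published summary statistics the
# Australian FASD prevalence analysis runs on. Each also ships in
# inst/extdata/scenarios.yaml for use from the command line.

#' Pooled Australian PAE prevalence
#'
#' Meta-analytic prevalence of prenatal alcohol exposure across 16 large
#' Australian general-population birth cohorts (studies published
#' 1975-2018): 48% (95% CI 38%, 57%), with an across-study range of
#' 14.2%-76%.
#'
#' @return A [summary_proportion()]. The study range is available as
#'   `attr(x, "range")`.
#' @export
pae_australia_pooled <- function() {
  s <- summary_proportion(0.48, 0.38, 0.57,
                          label = "PAE prevalence, pooled Australian birth cohorts 1975-2018")
  attr(s, "range") <- c(0.142, 0.76)
  s
}

#' NDSHS prenatal alcohol exposure prevalence
#'
#' Self-reported PAE prevalence among pregnant respondents of the National
#' Drug Strategy Household Survey: 29.7% (95% CI 25.3%, 34.1%) in 2019 and
#' 28.3% (95% CI 21.2%, 35.4%) in 2022-23. Used for sensitivity analysis
#' because survey data were excluded from the pooled birth-cohort estimate.
#'
#' @param year `2019` or `2022` (the 2022-23 wave).
#' @return A [summary_proportion()].
#' @export
pae_ndshs <- function(year = 2019) {
  if (year == 2019) {
    summary_proportion(0.297, 0.253, 0.341, label = "PAE prevalence, NDSHS 2019")
  } else if (year %in% c(2022, 2023)) {
    summary_proportion(0.283, 0.212, 0.354, label = "PAE prevalence, NDSHS 2022-23")
  } else {
    stop("no NDSHS PAE fixture for year ", year, call. = FALSE)
  }
}

#' Meta-analytic risk of FASD given PAE
#'
#' One case of FASD per 13 alcohol-exposed pregnancies (headline risk
#' 7.69%), with a 95% CI of (7.25%, 7.90%) derived from binomial sampling
#' over the source studies (pooled n = 158,161). The working mean used for
#' point estimates is 7.58%, the interval midpoint; see
#' [make_risk_model()] for why the two values are carried separately.
#'
#' @return A `risk_model`.
#' @export
fasd_risk_per_exposed <- function() {
  make_risk_model(13, c(0.0725, 0.0790), pooled_n = 158161)
}

#' Built-in scenario set
#'
#' The three published PAE scenarios (pooled birth cohorts, NDSHS 2019,
#' NDSHS 2022-23), all sharing the one-in-13 risk model. Identical to the
#' shipped config file `system.file("extdata", "scenarios.yaml", package =
#' "fasdprev")`.
#'
#' @return A `scenario_set`.
#' @export
default_scenarios <- function() {
  risk <- fasd_risk_per_exposed()
  pooled <- pae_australia_pooled()
  scenario_set(
    risk = risk,
    scenarios = list(
      scenario("Australia pooled birth cohorts", pooled, risk,
               pae_range = attr(pooled, "range"),
               source = "meta-analysis of 16 birth cohorts, 1975-2018"),
      scenario("NDSHS 2019", pae_ndshs(2019), risk, year = 2019,
               source = "National Drug Strategy Household Survey 2019"),
      scenario("NDSHS 2022-23", pae_ndshs(2022), risk, year = 2022,
               source = "National Drug Strategy Household Survey 2022-23")
    )
  )
}
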