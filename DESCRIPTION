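Package: fasdprev
Title: Indirect Estimation of Fetal Alcohol Spectrum Disorder Prevalence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the population prevalence of fetal alcohol spectrum
    disorder (FASD) from published summary statistics on prenatal alcohol
    exposure (PAE) and on the risk of FASD among exposed pregnancies.
    Fits beta distributions to proportions reported as a mean with a 95%
    confidence interval by moment matching, propagates uncertainty through
    the prevalence product by seeded Monte Carlo simulation with percentile
    confidence intervals, runs named sensitivity scenarios, converts
    estimates to per-1000 rates and affected-births counts, and validates
    interval coverage against synthetic multi-cohort birth data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
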