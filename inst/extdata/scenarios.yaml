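# Published inputs for the Australian FASD prevalence analysis.
# Schema: see ?read_scenarios.
risk:
  n_per_case: 13          # one FASD case per 13 alcohol-exposed pregnancies
  interval: [0.0725, 0.0790]
  pooled_n: 158161
scenarios:
  - label: "Australia pooled birth cohorts"
    mean: 0.48
    ci_low: 0.38
    ci_high: 0.57
    range: [0.142, 0.76]
    source: "meta-analysis of 16 birth cohorts, 1975-2018"
  - label: "NDSHS 2019"
    year: 2019
    mean: 0.297
    ci_low: 0.253
    ci_high: 0.341
    source: "National Drug Strategy Household Survey 2019"
  - label: "NDSHS 2022-23"
    year: 2022
    mean: 0.283
    ci_low: 0.212
    ci_high: 0.354
    source: "National Drug Strategy Household Survey 2022-23"
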