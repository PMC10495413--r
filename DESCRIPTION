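Package: pira
Title: Disability Accumulation Classification in Ocrelizumab-Treated
    Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying confirmed disability accumulation (CDA) in
    longitudinal multiple sclerosis cohorts under B cell-depleting therapy.
    Screens patients against eligibility criteria, detects EDSS worsening
    events on a roving baseline with 12-week confirmation, subtypes them as
    relapse-associated worsening (RAW) or progression independent of relapse
    activity (PIRA, with or without superimposed relapses), and runs the
    downstream time-to-event (Kaplan-Meier, covariate-adjusted Cox subgroup
    models), propensity-score and nonparametric group-comparison analyses.
    Includes a calibrated stochastic cohort simulator and a deterministic
    fixture cohort so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
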