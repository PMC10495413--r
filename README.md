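# pira

Disability-accumulation analysis for longitudinal multiple sclerosis (MS)
cohorts under B cell-depleting therapy.

In relapsing–remitting MS (RRMS), disability measured on the Expanded
Disability Status Scale (EDSS, ordinal 0–10 in half-point steps, with no 0.5)
worsens through two distinct mechanisms: **relapse-associated worsening
(RAW)** — a fixed deficit remaining after a relapse — and **progression
independent of relapse activity (PIRA)** — confirmed worsening with no
relapse anywhere near the qualifying interval. Separating the two on
real-world visit timelines is a fiddly windowing problem; this package
implements it as a tested, configurable pipeline for clinical researchers
working with registry or chart-review data.

## The event definitions

With visits \(t_1 < t_2 < \dots\) and the *roving reference* being the
previous assessment, a **confirmed disability accumulation (CDA)** event at
visit \(t_i\) requires

\[
\mathrm{EDSS}(t_i) - \mathrm{EDSS}(t_{i-1}) \ge
\begin{cases} 1.0 & \mathrm{EDSS}(t_{i-1}) \le 5.5\\
              0.5 & \mathrm{EDSS}(t_{i-1}) > 5.5 \end{cases}
\]

and confirmation at the earliest visit \(t_j\) with \(t_j - t_i \ge 84\)
days, the same threshold still holding versus the same reference (by
default also at every visit in between). The event is dated at \(t_i\).
Subtypes:

* **RAW** — at least one relapse in \((t_{i-1}, t_i]\);
* **PIRA** — no relapse in \((t_{i-1}, t_i]\) and none within 84 days
  before \(t_{i-1}\); on-treatment relapses outside that window make the
  patient "PIRA with superimposed relapses" (PIRA+SIR);
* anything else is `CDA_unclassified`.

The patient's label is determined by their first event. Around the
classifier the package provides eligibility screening (RRMS course, age
18–70, baseline EDSS ≤ 7.0, ≥ 6 months of follow-up, no relapse in the 90
days before therapy start), Kaplan–Meier estimates of time to first
CDA/PIRA/RAW (event time = the increase visit, in months), Cox
proportional-hazards subgroup models adjusted for age, sex, baseline EDSS
and baseline annualized relapse rate (ARR), logistic-regression propensity
scores for PIRA occurrence, and Mann–Whitney / Kruskal–Wallis + Dunn group
comparisons. Because registry data of this kind cannot be redistributed, a
calibrated stochastic cohort simulator and a deterministic 97-patient
fixture cohort (plus a 200-record pre-screening registry) are included; both
are synthetic.

## Worked example

```r
library(pira)

cohort <- generate_fixture_cohort()   # deterministic 97-patient cohort
cls <- classify_cohort(cohort)
cls
#> Disability-accumulation classification of 97 patients
#>   CDA : 23 (23.7%)
#>   PIRA: 20 (20.6% of cohort, 87.0% of CDA; 4 with superimposed relapses)
#>   RAW :  3 (3.1% of cohort, 13.0% of CDA)
#>   stable: 74
```

Of 97 patients, 23 (23.7%) carry a confirmed EDSS worsening; 20 of those
(87.0% of CDA) progressed without any relapse involvement — PIRA, not RAW,
dominates disability accumulation. Time-to-PIRA by disease-duration
quartile, adjusted for the remaining baseline covariates:

```r
surv <- build_survival_dataset(cls, cohort, "PIRA")
strata <- assign_strata(cohort, "disease_duration", "quartiles")
cox_fit(surv, strata)
#> Cox proportional-hazards model: 97 patients, 20 events (grouping: disease_duration)
#>                 term    hr  lower upper      p
#>  disease_duration:Q2 0.371 0.1250 1.100 0.0749
#>  disease_duration:Q3 0.137 0.0295 0.638 0.0113
#>  disease_duration:Q4 0.183 0.0401 0.832 0.0279
#>      age_at_baseline 0.990 0.9300 1.050 0.7570
#>                 sexM 1.420 0.5440 3.710 0.4730
#>        baseline_edss 0.984 0.7280 1.330 0.9150
#>         baseline_arr 0.837 0.3910 1.790 0.6460
```

Hazard ratios below 1 for the longer-duration quartiles: patients starting
therapy early in their disease course progress *more* often — the
indication-bias signature the fixture deliberately encodes. The whole
bundle (screening flow, outcome summary, group comparison, KM tables, all
Cox stratifications, propensity table) runs as one call:

```r
report <- run_analysis(list(), out_dir = "report")   # fixture input by default
```

`run_analysis` also accepts a YAML config selecting CSV input
(`visits.csv`, `relapses.csv`, `patients.csv`), a simulated cohort, or
non-default classifier windows. A thin command-line wrapper lives at
`inst/cli/pira-cli.R`.

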