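---
title: "Classifying disability accumulation in MS cohorts: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying disability accumulation in MS cohorts: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pira)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and how they were resolved.

## The classification procedure

A patient's record is an ordered series of EDSS assessments plus a list of
relapse dates. EDSS lives on the grid $\{0, 1.0, 1.5, \dots, 10.0\}$ — there
is no 0.5 — and the package validates this at every entry point, because a
half-point bookkeeping error is exactly the kind of mistake that silently
flips event calls.

**Roving reference.** The reference for a possible worsening at visit $i$ is
the immediately preceding assessment, re-set at every visit. It is *not* the
study baseline and *not* a re-baselined minimum. The definitions literally
compare "with the previous assessment", and the threshold rule speaks of the
*previous* EDSS; we read its one mention of a "baseline" EDSS in the
threshold rule as that same reference. A fixed-baseline variant would call
more events in slowly drifting trajectories; users can emulate coarser
conventions only by pre-processing visits, deliberately — the roving rule is
the method.

**Detection.** An increase at visit $i$ qualifies when it exceeds 1.0 point
(reference EDSS $\le 5.5$) or 0.5 point (reference $> 5.5$). It becomes a
CDA event when the earliest visit at least `confirmation_days` (84 d = 12
weeks) after $t_i$ still meets the threshold against the same reference.
Two sub-decisions were open:

* *Which visit confirms?* The earliest eligible one. If it fails the
  threshold the event is void — we do not scan later visits for a more
  agreeable confirmation, which would bias detection upward.
* *What about visits between increase and confirmation?* By default any
  intermediate visit below threshold voids the event
  (`require_sustained = TRUE`). "Confirmed" should mean the deficit
  persisted, not that it recurred on schedule. The lenient variant is a
  config flag.

A qualifying increase sustained over many later visits yields one event per
qualifying increase visit, not one per confirmation; the definitions do not
say, and dating events at the *first* of the two diverging assessments is
the convention we follow throughout (it also defines event time in the
survival analyses).

**Subtyping.** RAW requires a relapse in $(t_{ref}, t_{inc}]$; a relapse on
the exact day of a visit belongs to the interval *ending* there, since a
same-day relapse plausibly explains that visit's score. PIRA requires the
qualifying interval relapse-free *and* an 84-day relapse-free window before
the reference. By default (`pira_relapse_window = "to_increase"`) a relapse
between increase and confirmation does not void PIRA — the defining
interval is between the two diverging assessments — but counts as a
superimposed relapse; the stricter `"to_confirmation"` reading is available.
An event that is neither (relapse-free interval, but a relapse within 84 d
before the reference) is `CDA_unclassified`. The category is logically
necessary even though well-behaved cohorts may contain none; collapsing it
into PIRA would contaminate the primary outcome, into RAW would be simply
wrong.

**Labelling.** The first CDA event fixes the patient label; later events
remain in the event list. Superimposed-relapse status considers only
on-treatment relapses (on/after therapy start): pre-baseline relapses enter
the annualized relapse rate, not SIR.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `confirmation_days` | 84 | days | "12 or more weeks", at day granularity |
| `step_low_edss` / `step_high_edss` | 1.0 / 0.5 | EDSS points | standard confirmed-progression thresholds |
| `edss_cut` | 5.5 | EDSS points | where the step requirement halves |
| `pira_prewindow_days` | 84 | days | relapse-free run-in before the reference |
| `baseline_relapse_exclusion_days` | 90 | days | "three months" ≈ 90 d |
| `min_followup_months` | 6 | months | eligibility floor |
| `max_baseline_edss` | 7.0 | EDSS points | eligibility ceiling |
| `min_age` / `max_age` | 18 / 70 | years | eligibility range |

Calendar conversions are fixed: 30.44 d/month, 365.25 d/year. Follow-up,
event times and therapy duration are reported in months; disease duration
in years.

## Eligibility screening

Exclusions are logged once per patient with the *first* failing reason, in
the order: primary-progressive course → incomplete data (fewer than two
on-treatment EDSS assessments) → follow-up under 6 months → baseline EDSS
above 7.0 → age out of range → relapse within 90 days before baseline. The
ordering matters only for the flow log (a PPMS record with one visit counts
as PPMS), and mirrors how selection flow charts are conventionally reported.
Baseline EDSS is the first assessment on/after therapy start; no
interpolation. When no visit coincides with the first infusion this is a
convention, not a fact about the data.

## Synthetic data

**Stochastic simulator** (`simulate_cohort`). Emulates the study conditions:
97 patients by default, visits every ~180 ± 30 days, follow-up uniform over
6–51 months, baseline EDSS drawn from a grid-snapped normal (3.5 ± 2.2,
clamped to [0, 6.5]), pre-baseline relapses placed 91–730 days before
baseline at a rate targeting a mean ARR of 0.7, on-treatment relapse rate
0.05/yr (B cell depletion suppresses relapses), residual-deficit probability
0.3 per relapse interval, per-interval PIRA hazard 0.045, and transient
±0.5 EDSS noise at 5% of visits. Noise never persists at two consecutive
visits, so noise alone cannot satisfy confirmation — the confirmation logic,
not the generator, is the arbiter — but a downward blip at a reference visit
can still manufacture an apparent step, as in real measurement error.
Implanted steps are permanent and only placed where a confirming visit
exists; the generator logs every implant and every interval at risk of one,
so tests can check *closure* (with noise off, the classifier recovers the
log exactly) and *rate recovery* (implant frequencies within binomial
confidence bands of the hazards).

What the simulator does **not** model: MRI activity, treatment switching,
death or dropout correlated with worsening, functional-system subscores,
relapse severity, or EDSS floor/ceiling dynamics beyond clamping. Passing
tests therefore demonstrate algorithmic correctness under idealized
longitudinal sampling, not robustness to every real-world artefact.

**Deterministic fixture** (`generate_fixture_cohort`). Hard-coded timeline
archetypes — stable (optionally with a fully remitting relapse), RAW
(relapse at day 150, confirmed one-point step at day 180), PIRA without
superimposed relapses (one to three confirmed steps from day 180), PIRA
with a superimposed relapse at day 650 — combined 71/3/3/16/4 into a
97-patient cohort whose classification yields exactly 23 CDA, 20 PIRA and
3 RAW. Archetypes are hard-coded rather than sampled because the class
counts must be exact. Covariates follow fixed cycles approximating the
cohort's published marginals (age ≈ 42, 48/97 female, ARR ≈ 0.7, PIRA
patients with shorter disease duration and fewer prior therapies), with
worse-eye OCT values present for roughly 40% of patients. A companion
200-record registry fixture adds 56 PPMS, 33 incomplete, 7 short-follow-up
and 7 high-EDSS records for the screening flow. Both are synthetic
constructions, not patient data.

## Statistical components

* **Kaplan–Meier** via `survival::survfit`: product-limit estimate,
  Greenwood variance, events processed before censorings at tied times.
  Per-event-type curves censor at the last visit; RAW and PIRA are *not*
  treated as competing risks (the source analyses did not), so the CDA
  curve, which pools both, dominates each subtype curve — a relation the
  tests verify.
* **Cox models** via `survival::coxph`, Efron tie approximation (the better
  default for tied months; the tie method was not specified upstream), Wald
  intervals and p-values. Adjustment covariates (age, sex, baseline EDSS,
  baseline ARR) are dropped automatically when they define the grouping.
  Monotone-likelihood/separation warnings are promoted to errors; the
  pipeline records them per stratification instead of aborting.
* **Quartile stratification** uses linear interpolation of order statistics
  (type-7 quantiles) — the interpolation rule is not stated upstream and
  cutpoint values depend on it, which is why it is fixed and documented
  here. Values on a cutpoint go to the lower group.
* **Mann–Whitney U**: exact enumeration when both n ≤ 8 without ties,
  otherwise tie-corrected normal approximation with continuity correction.
  Two-sided throughout (sidedness was unstated upstream).
* **Kruskal–Wallis + Dunn**: tie-corrected H; Dunn pairwise z-tests with
  Bonferroni adjustment — "Dunn's multiple comparison test" names a family,
  and Bonferroni is the conventional companion, stated explicitly for
  reproducibility.
* **Propensity scores**: unpenalized maximum-likelihood logistic regression
  of PIRA occurrence on sex (0/1), baseline EDSS, baseline ARR and age
  (IRLS to relative tolerance 1e-12), fitted probabilities as scores,
  subgroup score distributions compared by two-sided Mann–Whitney. Complete
  separation raises an error rather than returning divergent coefficients.
  Scores are invariant to affine covariate rescaling, which the tests check
  to 1e-8.

Percentages in summaries are rounded half-up to one decimal, matching
clinical reporting style (base R's round-half-even would turn 23.65 into
23.6).

## Problem sizes and determinism

The test suite runs the brute-force oracle comparison on 200 random small
timelines (≤ 8 visits), closure on 200–250 simulated patients, calibration
and rate recovery at n = 500, and Cox hazard-ratio recovery at n = 400 with
null calibration over 200–300 replicates — sizes chosen so the full suite
completes in well under a minute while keeping Monte-Carlo bands tight.
All stochastic tests fix seeds; `simulate_cohort` is seeded through its
parameter object and is byte-reproducible.

## Known limitations

* Missed or unrecalled mild relapses can masquerade as PIRA; no imputation
  or sensitivity analysis is attempted.
* The classifier assumes honest visit dates and one EDSS per date; it does
  not model rater variability beyond the simulator's noise term.
* No competing-risk estimators, proportional-hazards diagnostics or
  time-varying covariates — deliberately out of scope.
* The fixture cohort reproduces class *counts* and marginal structure, not
  the full joint covariate distribution of any real cohort; conclusions
  about covariate effects drawn from it illustrate the machinery only.
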