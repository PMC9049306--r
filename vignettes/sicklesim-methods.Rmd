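---
title: "Model and methods: an individual-based microsimulation of sickle cell disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: an individual-based microsimulation of sickle cell disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sicklesim)
```

## The model

`sicklesim` simulates individuals with sickle cell disease (SCD) through
annual cycles from model entry (the index date, a notional opportunity to
receive curative therapy) until death or age 100. Health is tracked along
four parallel, non-exclusive dimensions — chronic pain, acute events,
chronic disorders, and treatment complications — so a person occupies a
*combination* of health states rather than one mutually exclusive state.
This avoids the combinatorial explosion of enumerating all configurations
of the 26 disease attributes (13 acute events, 7 subacute disorders
including chronic pain, 6 absorbing chronic disorders), while letting
disease history drive transitions, which a memoryless cohort Markov model
cannot.

Persistence semantics tie the simulated world to the claims world it is
parameterized from:

* **acute events** are instantaneous: they occur within a cycle, increment
  lifetime history counts, and carry no state into the next cycle;
* **subacute disorders** can remit: a disorder is *present* in a year if a
  qualifying event occurred in that year or the two preceding years (the
  standard claims lookback, implemented inclusive of the current year so a
  newly diagnosed disorder is present in its diagnosis year);
* **chronic disorders** are absorbing: present in every year from first
  onset. Chronic pain is drawn every year in its own dimension (subacute
  persistence) to reflect its central, fluctuating role in SCD.

Mortality can occur in any state: a Gompertz–Makeham background annual
probability by age and sex is combined with per-attribute hazard ratios on
the log-hazard scale, converted back to an annual probability, and clipped
to [0, 1]. No published mortality model accompanies the claims analyses
this package emulates, so the background parameters and hazard ratios are
package defaults, exposed in the configuration.

### Within-cycle order

Each cycle applies a fixed order: (1) age one year and clear acute events;
(2) treatment-use draws (hydroxyurea, acute and chronic transfusion);
(3) chronic/subacute incidence draws; (4) acute-event draws; (5)
complication draws given current treatment and any attempted curative
therapy; (6) utilization draws; (7) mortality. The order is a modeling
choice constrained by the covariate timing contracts of the prediction
indices (below): treatment use is decided before the year's acute events
are realized, so the treatment index conditions on chronic status carried
into the year, subacute activity within the two-year lookback, and
*previous-year* acute events. The index-fitting designs use exactly the
same information sets, keeping training and simulation consistent. No
half-cycle correction is applied: outcomes, utilities and costs count for
the full year lived, including the death year. These conventions are
stated here because they are genuinely open choices; alternatives (e.g.
half-cycle credit) would shift discounted totals slightly but none of the
structural conclusions.

## Prediction indices

Transitions are driven by four families of penalized logistic (and, for
utilization, log-link count) regressions, one index per outcome:

| family | outcomes | covariate timing |
|---|---|---|
| incidence | each of the 26 attributes | previous-year status, history, treatment, complications |
| treatment_use | hydroxyurea, acute/chronic transfusion | status at the treatment decision + history |
| complication | common-care complications | current-year status and treatment, history, lagged complications |
| utilization | inpatient, ED, outpatient counts | all current-year blocks |

Demographics enter every family as sex, 5-year age-band indicators, and
birth-decade indicators. History summaries are lifetime counts of each
acute event, years of chronic pain, and durations of chronic disorders.
Elastic-net penalties (default mixing 0.5) manage this covariate space;
the penalty strength is chosen by seeded 5-fold cross-validation on the
training split only, with stratified folds so rare outcomes keep events in
every fold. Outcomes too rare to cross-validate fall back to an
intercept-only index at the observed rate. Sample splitting is at the
beneficiary level (50% train / 25% first test / 25% held out), so no
person-year of a beneficiary leaks across parts; parameter uncertainty
comes from beneficiary-level bootstrap refits on the first test split.
Utilization uses Poisson log-link models — a package decision; the age
banding (5 years) and fold count (5) are likewise declared defaults, and
indices are fit independently per outcome rather than jointly.

## Synthetic claims world

Real public-payer claims (Medicaid, Medicare, dual-eligible) cannot be
shipped, so the package generates a synthetic claims world with the same
*structure*: month-granular enrollment spans with gaps, dated claims with
positioned ICD-9/ICD-10 codes (edition switching with service year),
treatment procedure flags, HSCT events, deaths, and non-case beneficiaries
emitting only noise (including occasional sickle-cell-trait codes) so case
identification has true negatives. Entry demographics reproduce the
published cohort moments (Medicaid mean age 16.9 years, SD 13.9, 53.4%
female; Medicare 62.3/16.2, 60.2%; dual 33.3/19.5, 58.1%): the age
distribution is a normal truncated at zero whose location is solved
numerically so the realised mean equals the published mean. Default
per-attribute annual claim probabilities are back-derived from the
published lifetime prevalences assuming a nominal five-year mean observed
follow-up, `p = 1 - (1 - P)^(1/5)` — a realistic claims intensity, not a
fit. The generator draws attributes independently within person-years;
real comorbidity correlation (e.g. renal disease co-occurring with
cardiovascular disease) is *not* emulated, and neither are race/ethnicity,
billing amounts, or CMS file layouts. Passing tests therefore demonstrate
that the estimation and simulation machinery is correct and calibratable,
not that the fitted coefficients equal those a real claims analysis would
produce.

The cohort builder then applies the claims-analysis rules exactly as a
real analysis would: case definition (one inpatient or two distinct-date
outpatient/ED claims with an SCD code in any position, trait codes
excluded), index date (first in-span SCD claim), a 12-month continuous
enrollment requirement, only the longest enrollment period per beneficiary
(ties to the earliest), censoring at death, disenrollment, the year before
HSCT, or the window end, and the persistence semantics above. Where the
source rules are ambiguous we chose: the two-year subacute lookback
includes the current year; partial first/last years count as whole panel
years; the death year is a full person-year; the disenrollment year is
dropped when the span ends mid-year (conservative), except when the span
ends because of death. The attribute ICD code lists shipped in
`inst/extdata/registry.yaml` are illustrative defaults (the validated
lists are not published in full) and are fully overridable.

## Calibration

Because claims under-capture pain and the synthetic world is only
structurally faithful, simulated lifetime prevalences are calibrated to
the published lifetime-prevalence table (`prevalence_targets()`) by a
per-attribute one-dimensional root search on each incidence intercept
(a log-odds shift). The searches share simulations: each global pass
simulates one Common Care cohort under the current shifts (with common
random numbers across passes, so the search sees a deterministic
objective) and applies a damped logit-scale step to every attribute,
secant-refined once two evaluations exist. Near-separability of
intercept → own-prevalence makes this converge in a handful of passes; the
shared passes absorb cross-attribute feedback (e.g. through mortality
hazard ratios). Defaults: 2,000 simulated individuals per pass, tolerance
2 percentage points, at most 8 passes; unreachable targets (e.g. 0% for an
attribute with a structural floor) are flagged rather than fatal.
Calibrated models are verified on an independent seed at 10,000
individuals. `validate_external()` provides the companion hook for
comparing simulated statistics against published non-claims estimates
(e.g. survey-based pain-episode rates) without adjusting anything.

## Strategies and economics

Common Care (no treatment, hydroxyurea, or transfusion, without HSCT) is
the comparator. Curative strategies (HSCT, gene therapy) are applied at
model entry to individuals meeting a severity rule — by default a lifetime
history of at least three severity-marked acute events (vaso-occlusive
episodes, acute chest syndrome, multi-organ failure, stroke) or any stroke;
the rule is a declared assumption, configurable, because the source
defines severity only as "history of severe adverse events". A durable
response is drawn once (default probability 0.90 for HSCT, 0.85 for gene
therapy); responders' incidence probabilities are multiplied by per-
attribute risk ratios (default 0, full suppression) and responders come
off common-care treatment, while non-responders keep Common Care dynamics.
Both carry the attempted therapy's complication risks (first-year and
subsequent annual probabilities; graft-versus-host disease only for HSCT).
A waning scenario decays suppression toward no effect with a configurable
half-life. Baseline severe-event history at entry is drawn from simple
age-scaled processes so entry eligibility is non-trivial.

Annual utility is a base value by age band minus additive decrements per
active attribute and complication, with the chronic-pain decrement applied
in parallel, clamped to [0, 1]; optional pairwise interaction terms are
available, and additive-with-clamp was chosen over multiplicative
combination for transparency. Societal costs add to medical costs
(utilization × unit costs + treatment costs + one-time therapy price):
time-use/productivity cost linear in the utility shortfall,
`(1 − u) × hours × wage`, a transparent stand-in for time-use-survey based
estimates; unpaid caregiver time (child/adult rates, applied in years with
active disease); age-specific future unrelated medical costs; and an
end-of-life cost in the death year. Caregiver utilities are excluded (no
published estimates). Both costs and QALYs are discounted at 3% per year
(US convention; configurable). ICERs are computed along the non-dominated
frontier with strict and extended dominance flagged; probabilistic
sensitivity analysis redraws bootstrap coefficient replicates and
gamma/beta-style cost and utility parameters per draw, reruns reduced-n
cohorts with common random numbers, and summarizes the draw cloud as a
cost-effectiveness acceptability curve.

## Reproducibility and numerics

One master seed feeds named substreams per stage, and each simulated
individual consumes its own seeded uniform stream by fixed (year, channel)
position — so cohorts are bit-reproducible, growing a cohort leaves
earlier individuals' trajectories unchanged, and the single-person and
vectorised code paths are identical. Probabilities are validated to [0, 1]
after treatment effects (a bad risk ratio raises an error naming the
attribute); prevalences are clamped away from 0/1 on the logit scale
during calibration; utilization rates are capped at 365/year.

Problem sizes used by the shipped demo and tests — cohorts of a few
hundred to a few thousand beneficiaries, calibration at 2,000 individuals
per pass, verification at 10,000 — were chosen so that every property of
interest is measured well inside Monte-Carlo noise while the full pipeline
stays a minutes-scale desktop computation.

## Known limitations

Annual cycles blur within-year event ordering; no donor availability or
treatment timing beyond entry is modeled; the synthetic generator omits
comorbidity correlation and sociodemographic structure; utility decrements
and cost parameters are placeholders to be replaced by mapped health-state
utilities and costed impact-inventory estimates when available; and the
calibrated coefficients describe the synthetic claims world, not any real
payer population.
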