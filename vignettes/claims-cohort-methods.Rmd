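---
title: "Claims-based cohorts for elderly-onset ulcerative colitis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based cohorts for elderly-onset ulcerative colitis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucclaims)
```

## The problem

Administrative prescription-claims databases record diagnoses, prescriptions
and procedures, but not clinical onset dates or treatment courses. To study
ulcerative colitis (UC) in the elderly with such data, three derived
constructs are needed, and each is a modelling decision rather than a fact
of the data:

1. **Who has new-onset UC, and when?** UC cases are identified by ICD-10
   code K51 (excluding records flagged "suspicious" and patients with any
   Crohn's K50 code). The onset date is proxied by the earliest *new*
   prescription of an induction-capable class — 5-ASA, systemic steroid, or
   topical steroid — where "new" means no same-drug prescription in the
   preceding 26 weeks (182 days).
2. **Who is elderly-onset?** Patients aged at least 65 at the end of
   observation are kept and split by age at onset: elderly-onset (EO, onset
   at ≥65) versus non-elderly-onset (NEO, onset before 65 in a patient who
   reaches 65 during observation). The 65-year threshold follows the WHO
   definition of elderly.
3. **When does a treatment start and stop?** Claims contain refill events,
   not exposure intervals. Prescriptions are assembled into *exposure
   episodes* using drug-specific scheduled-refill rules; an episode is
   discontinued when no refill arrives for more than 13 weeks (91 days)
   after the next scheduled prescription date.

Downstream, the package estimates steroid-free, MTD-free (molecular
targeting drug: biologics plus small molecules) and surgery-free survival
from onset, treatment persistence of the first MTD, and multivariable
outcome models.

## The episode engine

Each drug carries one refill rule, configured in the packaged catalog:

| rule | drugs | next scheduled date |
|---|---|---|
| fixed 12 weeks | ustekinumab | last prescription + 84 days |
| fixed 8 weeks | infliximab, vedolizumab | last prescription + 56 days |
| count × 14 days | adalimumab, golimumab | last prescription + 14 × dispensed count |
| prescription days | all others | last prescription + dispensed covered days |

Weeks are exactly 7 calendar days; no month arithmetic is used, so all date
math is integer and reproducible. The engine scans each patient-drug claim
history once. A prescription at most 91 days after the scheduled date
extends the episode and re-anchors the schedule; a later one closes the
episode as discontinued and opens a new episode. After the final
prescription, the episode is discontinued if censoring lies more than 91
days past the scheduled date, otherwise it is ongoing at censoring.

Numerical conventions, each isolated and fixed by a unit test:

- *Washout window is half-open.* "Within 26 weeks before" is the interval
  `[rx − 182, rx)`: a prior prescription at exactly 182 days does **not**
  disqualify; at 181 days it does.
- *The discontinuation gap is strict.* A refill exactly 91 days past the
  scheduled date still continues the episode; discontinuation requires a
  gap *greater than* 13 weeks.
- *Discontinued episodes end on the last scheduled date*, not at gap
  detection, so persistence curves do not credit uncovered waiting time.
  The alternative convention (end at scheduled + 91) would shift every
  persistence time by a constant for fixed-interval drugs; the choice is
  confined to one branch of `build_episodes()`.
- *Same-day duplicate claim lines merge* before episode construction, with
  dispensed amounts summed. Dispensed counts for the count × 14 drugs never
  pool across claim dates.
- *Covered days are the union* of per-prescription coverage intervals, so
  early refills do not double-count days.

```{r episode-demo}
cat <- default_drug_catalog()
build_episodes(as.Date("2020-01-01") + c(0, 121), c(30L, 30L),
               catalog_get(cat, "prednisolone_po"),
               censor_date = as.Date("2020-07-01"))
```

## Onset estimation: course-level washout

The new-onset condition is evaluated at treatment-course level. Qualifying
prescriptions (5-ASA, systemic or topical steroid) are first assembled into
episodes; every *episode start* must pass the 26-week washout against the
full same-drug history. Refills inside a continuous episode belong to the
course that opened them and are not separately classified — otherwise every
maintenance 5-ASA patient (whose refills arrive every few weeks) would be
rejected, and no new-onset cohort could exist. A restart that clears the
91-day discontinuation grace but falls inside the 182-day washout *is* an
"old" start and drops the patient as prevalent or irregular use: this
situation arises exactly when a course's per-script coverage is shorter
than 91 days. For the same reason, "every episode start is new" is not a
theorem of the definitions; it holds for clean incident histories (and for
everything the bundled generator emits) but not universally.

A first prescription less than 26 weeks after observation start has
insufficient lookback to verify washout. Such onsets are still classified
new — absence of evidence of prior use — but the record carries a
`lookback_short` quality flag so sensitivity analyses can drop them.

Birth dates carry year and month only (the granularity of the source
database). The day is treated as the 1st and age is computed in completed
calendar years, which is deterministic and at most one month conservative.
The generator keeps simulated onset ages clear of the 65.0 boundary so this
rounding cannot flip an intended onset group.

## The synthetic claims generator

`generate_claims()` emulates the statistical structure the analysis relies
on, not the clinical texture of real Japanese claims. Defaults are the
study conditions:

- observation window 2014-04-01 to 2022-02-28;
- elderly-onset share 0.906 among eligible patients, male fraction 0.565,
  academic-facility flag 0.54%;
- onset ages: elderly component 65 + Exp(mean 7) years, pre-elderly
  component uniform on 57.5–64.6 (constrained to reach 65 in the window),
  plus a small young-onset component (mean 25) exercising the under-65
  exclusion;
- steroid, MTD and surgery initiation: exponential times from onset with
  group-specific rates `-log(S5)/1826` per day calibrated to the reference
  5-year event-free values (steroid 0.576/0.686, MTD 0.888/0.929, surgery
  0.975/0.985 for EO/NEO);
- death: Bernoulli from a logistic model with baseline (NEO, no steroid)
  probability 0.0072 and odds ratios 6.18 for elderly onset and 1.65 for
  steroid use. Death is drawn from a logistic model rather than a hazard
  because death is analysed as odds ratios in this design, while the
  time-to-event outcomes are analysed through KM curves and hazard models — each
  downstream fit can then recover its own generating parameters;
- maintenance 5-ASA as 30-day scripts with ±7-day refill jitter — well
  inside the 91-day grace, so episodes stay continuous unless a
  discontinuation is simulated; steroid courses as log-normal total covered
  days (median 61 oral / 10 intravenous); first-MTD choice from the
  reference per-group frequency table; MTD persistence exponential with
  mean 540 days;
- contamination paths (suspicious-only diagnoses, Crohn's co-diagnosis)
  with configurable probabilities.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: coding practice beyond K51/K50, dose
changes, switching motivated by clinical state, informative censoring,
regional or facility clustering, and any correlation between steroid use
and MTD/surgery hazards beyond the shared onset group. One known
approximation: when a simulated death falls before a drawn steroid
initiation, the death date is resampled after it, slightly distorting the
joint timing (but not the indicators the logistic model uses).

Determinism: one seed drives the whole bundle; identical configurations and
seeds give byte-identical tables.

## Estimation choices

- Kaplan–Meier estimation, the log-rank test, Cox proportional hazards and
  logistic regression are delegated to the `survival` package and `glm`;
  the test suite holds them against independent brute-force oracles
  (hand-rolled product-limit, hypergeometric-moment log-rank,
  expected-count chi-square, 2×2 cross-product odds ratio).
- Death is treated as right-censoring for the steroid/MTD/surgery curves,
  matching plain KM practice; with ~4% mortality the competing-risk bias is
  small, but cumulative-incidence estimates would be the rigorous
  alternative. This is a documented limitation, not an oversight.
- The 5-year readout is 1826 days (365.25 × 5, rounded).
- Cox models use the Efron tie correction: claims dates are day-granular
  and heavily tied.
- The three time-to-event outcomes are modelled with proportional hazards
  (hazard ratios); death, a rare terminal event without a natural time
  origin in this design, is modelled with logistic regression (odds
  ratios). Both families are available through `fit_outcome_model()` so
  either modelling reading can be reproduced.
- Group comparisons use Pearson chi-square without continuity correction;
  Fisher's exact test is available as an explicit alternative, because with
  counts as sparse as two deaths in a group the two tests differ visibly
  and statistical-software defaults vary. Neither is forced to agree with
  the other.
- Percentages in summary tables round half-up to one decimal, the
  conventional one-decimal table format.
- Degenerate fits (zero events, separated covariates) raise explicit
  errors naming the covariate rather than returning unstable estimates;
  the analysis drivers drop a separated covariate and say so. With a 0.54%
  academic-flag prevalence and sub-1% non-elderly mortality, separation is
  an expected feature of realistic replicates, as it is of the real data
  scale.

## Problem sizes

The bundled analyses and tests run at deliberately moderate scales chosen
for tight-but-honest statistical checks: cohort pipelines at 250–6000
patients, calibration experiments at the reference group sizes (2669 and
2770 for the KM readouts) and n = 20 000–30 000 for effect-size recovery,
where the 3-standard-error recovery bands are a few percent wide. The
episode-engine oracle sweep enumerates random claim histories of up to 5
prescriptions over 600 days for every refill-rule class against a
day-by-day scanner that re-derives coverage and gap status directly from
the definitions.

## Known limitations

- The onset proxy inherits the claims-phenotyping caveats: no chart
  validation, and a first prescription early in observation may be
  prevalent use (flagged, not excluded).
- Competing risks are not modelled (see above).
- The generator's independence assumptions make covariate effects cleaner
  than reality; recovery tests validate the estimators, not the clinical
  model.
- Steroid exposure enters outcome models as an ever-use indicator, as in
  the reference design; no immortal-time correction is attempted.
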