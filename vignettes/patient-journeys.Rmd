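---
title: "Reconstructing GPP patient journeys from claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing GPP patient journeys from claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppjourney)
```

## The problem

Generalized pustular psoriasis (GPP, ICD-10 L40.1) is a rare relapsing
skin disease treated with a wide mix of oral systemics, biologics,
apheresis and topicals, frequently in combination and with no settled
sequencing.  Claims databases record this history only as dated
diagnosis and prescription rows.  This package reconstructs from those
rows the quantities a treatment-pattern study needs — treatment
episodes, numbered lines of therapy (LOT), time-to-next-therapy (TTNT),
per-drug drug survival, switching and combination summaries — together
with a synthetic claims generator whose ground truth makes every stage
of the reconstruction testable.

All dates are calendar dates; every interval in the package is half-open
`[start, end)`, which prevents double counting when one period ends on
the day another begins.  Internal arithmetic is in integer days; months
appear only at reporting, through a single conversion
(`months_from_days()`, 30.4375 days per month = 365.25 / 12).  Rows with
unparseable dates are rejected with a located error and kept in the
bundle's `parse_errors` table rather than imputed — claims analyses must
be auditable.

## Cohort rules

The index date is the earliest *confirmed* L40.1 diagnosis inside the
enrolment window (2016-01-01 to 2021-08-31 by default).  Patients are
excluded when they have no such diagnosis (`unclear_history`), when all
their confirmed GPP diagnoses fall on a single service date
(`single_gpp_diagnosis` — two records on one day count as one
occurrence), or when follow-up is not strictly greater than 365 days —
unless death occurred within that span (`insufficient_followup`).
Follow-up ends at the earliest of study end, death, and last recorded
claim activity; the database model has no explicit disenrollment, so the
last claim defines loss to follow-up.  Sources without a
suspected-diagnosis flag default `confirmed` to `TRUE`; the flag exists
in the model because the exclusion rules require it.

Baseline comorbidity is the Charlson index over Quan's ICD-10 condition
groups with the original Charlson weights, computed on confirmed
diagnoses in `[index − 365 days, index)`.  The three standard hierarchy
rules apply (metastatic cancer over any malignancy, severe over mild
liver disease, complicated over uncomplicated diabetes).  The
psoriasis-vulgaris subgroup flag (L40.0) uses any-time presence by
default because it describes comorbid disease rather than a baseline
covariate; `psv_baseline_only = TRUE` restricts it.  Age thresholds
(≥65, ≥75) are inclusive and use age at index computed from birth year.

## Episodes

Each prescription covers `[date, date + days_supply)`; when the supply
is absent (typical for injectables) the drug's default coverage duration
from the catalog is used (28 days for most biologics, 56 for q8w dosing,
84 for q12w dosing such as ustekinumab, 30 for orals and topicals, 1 day
per apheresis session).  Coverage intervals of one patient-drug merge
into an episode when the lapse from the covered end to the next fill is
at most the drug's discontinuation gap: 3 months for biologics, 2 months
for oral drugs.  With the 30.4375-day month these round to **91** and
**61** days; the threshold for classes with no stated gap (topicals,
apheresis, arthritis treatments) is set to the oral 61 days, and any
threshold can be overridden per drug.  The gap is measured from coverage
end, not fill to fill, because a discontinuation is time *off* drug.

Overlapping coverage truncates by default — an episode never extends
beyond the latest covered end.  This is the conservative reading of
stacked fills; a stockpiling mode (`stockpile = TRUE`) that carries
unused days forward is available for sensitivity analyses.  The merge is
a sorted sweep; tests verify it against an independent brute-force
transitive-closure merger on randomized inputs, together with
monotonicity (episode count non-increasing in the gap) and idempotence.

## Lines of therapy

The catalog (12 treatment categories, priority ranks 1–12) classifies
every drug as *main* or *supplementary*; topicals, other oral
medications and arthritis treatments are supplementary.  Episodes are
lifted to the category level — drugs of one category pool, and
within-category lapses up to the category's gap threshold are bridged —
and a sweep line partitions `[index, followup_end)` into states of
constant composition.  The line rules are then:

1. a main category starting within `combination_window_days` (default
   30) of the current line's start *joins* it as a combination;
2. a later main start is an *add-on*: a new line of all then-active main
   categories;
3. after all main drugs end, the next main start is a *switch*: a new
   line regardless of similarity (same-category resumes within the gap
   threshold were already bridged away, which also implements the
   "identical regimen resuming within its gap continues the line" rule);
4. discontinuing one component of a combination opens a new line of the
   remaining categories;
5. supplementary starts and stops never change a line while a main drug
   is active — they only add the "+ supplementary drug" label suffix;
6. periods of supplementary-only treatment form their own line, labelled
   by the highest-priority supplementary category present.

The 30-day combination window is the common claims-LOT convention for
treating near-simultaneous starts as one prescribing decision; it is
configurable and logged.  Because window joiners update the line's
founding set, the active set always equals the founding set at state
boundaries, so rule 4's "remaining set equals the founding set" escape
is vacuous: any component discontinuation opens a new line.  Drugs
starting on the same date need no tie-break — they join one regimen.
Untreated gaps shorter than the component thresholds never appear as
states (the bridging absorbed them); longer gaps end the line at its
last covered day.  A supplementary-only period must span at least
`min_supp_lot_days` (default 1 day) to count as a line; real data can
produce short supplementary tails after a main line ends, and raising
this floor suppresses such slivers.

Each line's *general regimen* is its member category with the smallest
priority rank.  One documented exception is available:
`apheresis_dominates = TRUE` labels any combination containing
apheresis/plasma exchange with apheresis, matching the reporting
convention in which apheresis-based combinations are grouped under
apheresis even though cyclosporin outranks it; the default follows
strict priority.  The *specific regimen* joins the sorted category
names with `" + "` (radix sort, so the ordering is locale-independent)
plus the supplementary suffix.

## Survival machinery

TTNT is the start of one line to the start of the next; a patient's last
line is censored at the end of follow-up.  Drug survival pools all
episodes of all recipients of a drug; each patient's last episode of
that drug is censored and earlier episodes are events.  That convention
is implemented literally even when the last episode ends long before
follow-up ends — an alternative policy
(`censor_last_policy = "near_followup"`) censors the last episode only
when it ends within its gap threshold of follow-up end, for sensitivity
analyses (synthetic cohorts where most drugs occur once per patient
yield all-censored samples under the literal rule, so the sensitivity
policy is the useful one there).

The Kaplan–Meier estimator is implemented in the package:
`S(t) = ∏_{t_i ≤ t} (1 − d_i/n_i)` over distinct event times, units
censored at an event time counted at risk at that time, Greenwood
variance `S(t)² Σ d_i/(n_i(n_i − d_i))` (zero, not undefined, where the
curve reaches 0).  The median is the smallest event time with
`S(t) ≤ 0.5` (absent when the curve never reaches 0.5 — never
extrapolated), and its 95% interval inverts the pointwise log-log
confidence band, the most common choice in survival software; bounds
the data cannot determine are reported as `Inf`.  A half-interval
comparison tolerance of 1e-12 guards against floating-point ties at
exactly 0.5.  The observed range accompanying medians uses event
durations only.  The >1-year/>2-year on-drug proportions use cumulative
per-patient days on drug (thresholds 365.25 and 730.5 days);
`duration_basis = "longest"` switches to the longest single episode.
`survival::survfit` serves as an independent oracle in the test suite —
curves and variances agree to 1e-10; median conventions differ only at
exact-0.5 ties, where that implementation averages adjacent times.

Descriptive surfaces are exact counts: Sankey flows per line with an
explicit "No further therapy" sink (outflows sum to each regimen's
patient count — asserted, not assumed), combination frequencies with an
at-least-one-day episode overlap criterion, and bio-switching measured
from each patient's last episode of an index biologic to the first
different biologic starting afterwards within follow-up (denominators
are patients, restarts of the same drug are not switches, and the
destination window is unbounded within follow-up unless capped).

## The synthetic generator

`generate_cohort()` walks each patient through a pathway grammar —
regimen nodes with exponential or Weibull duration distributions and a
transition matrix — and emits prescriptions at the stated cadence,
at least two confirmed L40.1 diagnoses, follow-up visit records out to
the intended end of follow-up, baseline comorbidity codes, deaths, and
demographics (age ~ N(57.2, 19.9²) truncated to 18–95, 47.5% male,
36.6% psoriasis-vulgaris prevalence — the field's reported cohort
structure).  Everything flows through the documented CSV bundle schema;
the generator has no private channel into the pipeline.

Ground truth is defined under the pipeline's documented conventions, and
the three conformant presets are constructed to keep it unambiguous:
consecutive regimens share no treatment category, transition gaps are
drawn from 100–170 days (above both discontinuation thresholds) unless
configured contiguous, every drug in a regimen has its final fill forced
so coverage ends on one shared date (otherwise the staggered tail of a
combination would trigger the component-discontinuation rule and split
the line), cadence jitter is bounded at 20 days (well below 61), and
supplementary attachments are nested inside their main regimen's span.
The `edge_cases` preset is hand-built and deterministic: the
single-diagnosis patient, the short-follow-up survivor, the
death-within-a-year patient, a single-prescription patient, a same-day
combination start, and a repeated biologic episode with a
supra-threshold lapse, each with documented expected outcomes.

What the generator does **not** emulate: dose changes, in-hospital
administration, coding errors, rule-boundary ambiguity (overlaps that
straddle the combination window, supplementary tails), launch-year
effects, or realistic marginal frequencies beyond the coarse preset
mixes.  Passing the recovery tests therefore shows the algorithm
implements its stated rules exactly — not that those rules resolve every
ambiguity a real claims stream can produce.

`inject_noise()` perturbs a generated bundle in two labelled ways:
sub-threshold fill jitter (capped at 40 days, so that with the
generator's own cadence slack no lapse can reach 61 days; episode
counts provably unchanged) and supra-threshold gap injection (must
exceed the target drug's threshold; splits exactly one episode and
updates the episode ground truth).  A specification that crosses a
threshold without being relabelled is an error.

## Test and verification sizes

The suite verifies episode merging against the brute-force oracle on
500 randomized sets of up to 12 intervals; line recovery on the three
conformant presets at 300 patients × seeds 1–5 (4500 patients, 100%
exact agreement required); the Kaplan–Meier curve against the reference
implementation on 200 randomized samples at 1e-10; the closed-form
exponential median (6.0 months, n = 2000 event-only samples, within 5% —
the Monte-Carlo error of a sample median at that n is about 1.9%, so 5%
gives headroom without hiding real defects); and a derived first-line
TTNT median on a contiguous-transition pathway at n = 400 within 10%.
These sizes were chosen to exercise the estimators well past their
asymptotic regime while keeping the full suite fast enough to run on
every change.

## Known limitations

* The LOT rules are deterministic but, like every claims-LOT algorithm,
  a modelling choice; the combination window, gap thresholds and
  supplementary handling materially shape line counts and should be
  varied in sensitivity analyses (all are `journey_config()` fields).
* Age uses birth year only (claims rarely carry full birth dates), so
  ages are accurate to ±1 year.
* `drug_survival_table()` reports a missing median whenever censoring
  keeps the curve above 0.5 — common for drugs that patients receive in
  a single episode under the literal last-episode-censored rule.
* The validator reports referential and temporal inconsistencies but
  does not attempt repair; upstream data quality is the analyst's
  responsibility.
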