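---
title: "Inferring pregnancy episodes, outcomes, and start dates from OMOP-style EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring pregnancy episodes, outcomes, and start dates from OMOP-style EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipps)
```

## The problem

Electronic health records rarely state "this person was pregnant from date
A to date B with outcome C". Instead the pregnancy is scattered across
coded events: "Gestation period, 24 weeks" observations, trimester-specific
screening procedures, and (sometimes) a delivery or abortion code. Records
are duplicated, missing, or historically misdated, and a person can be
pregnant more than once in an observation window. **hipps** reconstructs,
for each person, a set of non-overlapping *pregnancy episodes*, each with
an outcome category, a support-flag pair from two independent inference
routes, a 0–2 outcome concordance score, and an estimated last menstrual
period (LMP) with an explicit precision category.

Gestational age throughout is measured in days or weeks from the LMP; one
"gestational month" is `365.25/12 = 30.4375` days (configurable), because
input rules mix day units ("60 days") and month units ("2 months") and the
conversion must be explicit.

## The inference stages

### HIP: hierarchy-based inference

*Outcome-based episodes.* Outcome records are processed category by
category in priority order — live birth > stillbirth > ectopic >
spontaneous abortion > induced abortion > delivery-record-only. Within a
category, a greedy date scan keeps only records separated by the
same-category minimum (182 days for live births, 168 for stillbirths);
survivors are then checked against retained higher-priority records (a
stillbirth must follow a live birth by ≥168 days or precede it by ≥182).
Pairs not stated by the method default to 56 days and are configurable in
`hierarchy_config()`. The procedure is idempotent.

*Gestation-based episodes.* "Gestation period, X weeks" (GW) records give
week-level gestational age at the record date. A record whose week fails to
increase marks a potential new episode; the split is accepted only if its
back-projected start (`date − 7·week`) clears the span of the current
draft, otherwise the record is noise and is excluded from delineation
entirely (so a stale historical record cannot corrupt the episode's
back-projection). Each draft's start is back-projected from its maximum
week (ties: latest record date).

*Merge.* An outcome joins the latest-starting draft whose plausible extent
`[start, start + term_max]` contains it. If the draft's maximum gestational
age (7·max_week days) falls outside the outcome's expected term-duration
window, the outcome is treated as misclassified and stripped. Lone outcomes
become episodes with `start = outcome_date − term_max`. Term windows
default to: live birth / stillbirth / delivery-only (140, 301) days,
ectopic (14, 84), abortions (14, 168); only the live-birth maximum of 301
days (43 weeks) is method-anchored — the rest are documented, configurable
assumptions.

### PPS: progression-signature inference

A separate route uses clinician-vetted concepts with tight expected
gestational windows (span > 1 week and ≤ 3 months). Two timed events are
*compatible* when the days between them can be explained by their windows:

```
delta ∈ [max(0, b.min − a.max), b.max − a.min] × days_per_month
```

A date-ordered scan extends the current episode when the event is
compatible with at least one member; otherwise a new episode starts only if
the gap from the immediately preceding scanned event is at least the
60-day retry period, else the event is held out as noise. Cleanup removes
episodes recorded longer than 12 months and all episodes of persons with
more than 5 episode starts in any sliding 365-day window (sliding was
chosen over calendar-year binning, which is boundary-sensitive). Outcomes
are then attached from a window of 14 days before the episode's last record
up to the earlier of the next episode's start and
`last_record + (10 − last record's min month) months`; that window end is
anchored at the last record's date because anchoring at the episode start
could place the window end before the last record. Among in-window
outcomes the hierarchy's highest priority wins, earliest date breaking
ties.

The test-suite checks this scan against an independent exhaustive oracle
that recursively enumerates all {extend, start-new, noise} assignments
under the same local predicates and verifies both uniqueness of the valid
segmentation and equality with the scan.

### Merge, concordance, ESD

HIP and PPS episodes are paired on interval overlap; conflicts resolve
greedily by closest end dates, pairs merge to their union with both support
flags, and leftovers pass through with one flag. An episode's final outcome
and 0–2 score come from `concordance()`: 2 = categories match within 14
days and the estimated gestational age at the outcome is inside the term
window; 1 = in-window but no cross-algorithm match (including when only one
algorithm found an outcome — the ladder's unstated single-sided case is
scored 1, since no cross-algorithm match exists); 0 = out-of-window even
with a match. On mismatch the later outcome is kept.

ESD estimates the LMP inside each episode. GW records are deduplicated per
date (keep max week) and back-projected to point candidates; each GR3m
(ranged) record back-projects to an interval. A GW candidate is removed
only when it lies outside the intersection of the GR3m intervals *and*
outside the Tukey fences (`1.5·IQR`, type-7 quantiles — fixed for
determinism) of the GW candidates; with fewer than 3 candidates the fence
condition never removes; conflicting GR3m intervals (empty intersection)
are discarded for filtering. The conjunctive reading is deliberately
conservative; `conjunctive = FALSE` gives the disjunctive variant for
sensitivity analysis. The retained GW record with the latest date supplies
the start; the window of retained starts maps to the precision ladder
(week ≤ 7 d, two-week ≤ 14, three-week ≤ 21, month ≤ 28, two-months ≤ 56,
three-months ≤ 84, else non-specific; a single supporting GW record is
"week_poor-support"). The baseline comparator uses all GW candidates,
no filtering, no ranged evidence.

### Annotation

COVID-19 positivity is the first in-episode positive PCR/Ag result or
diagnosis code; screening is any in-episode test regardless of result;
reinfection is a later positive ≥ 60 days after the index. Cohort 1 = all
episodes; cohort 2 = outcome (excluding delivery-record-only) with
month-level-or-better precision (week_poor-support included); cohort 3 =
outcome, score 2, week precision. Pandemic strata key on the episode *end*
date versus 2020-03-01 (the method does not say which date anchors the
split; end date is the documented choice) and on in-episode positivity.
Outcome-less episodes younger than the minimum plausible delivery length
(140 days) are flagged ongoing.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` is the package's stated world. Defaults: 500 persons,
1.2 pregnancies per person in expectation (`P(1)=0.8, P(2)=0.2`), outcome
mix 60% live birth / 4% stillbirth / 4% ectopic / 12% spontaneous abortion
/ 8% induced abortion / 4% delivery-only / 8% never-coded, GW records at
prenatal visit weeks 8, 12, …, 36, gestational lengths from per-outcome
discretized truncated normals (live-birth mode 273 days = 39 weeks,
matching the national modal gestation), first LMPs uniform over
2018-03–2020-12. GW records are emitted exactly at `LMP + 7·week` — no
date jitter — so noise-free back-projection recovers the LMP exactly; this
is what lets the recovery tests assert equality rather than tolerance.
Timed concepts are drawn uniformly inside their expected windows with a
0.05-month margin so day rounding never crosses a window boundary.
Consecutive pregnancies are separated by 290–420 days, which simultaneously
guarantees the 60-day retry, every outcome-separation minimum, and
cross-pregnancy incompatibility of timed concepts (two windows of span ≤ 3
months can never explain a gap > 183 days).

`corrupt_events()` adds the three noise channels the inference must
survive: GW dropout, outlier GW insertion (back-projected start off by
> 28 days), and historical held-out records dated before the first
pregnancy. A green test therefore establishes that the *rules* are
implemented faithfully and recover a compatible world — not that the
package reproduces registry-scale prevalence, site heterogeneity,
care-utilization patterns, or vocabulary drift, none of which the
generator models.

## Numerical and degenerate-input choices

- Dates are day-resolution throughout; age is completed years at the
  reference date (per-person earliest event by default).
- Interval overlap is closed-interval intersection of ≥ 1 day.
- Overlapping episodes that survive merging are *clipped* (later start
  moved to the previous end + 1 day) rather than fused: fusing an
  outcome-only episode, whose start is a 301-day back-projection, into the
  preceding episode would silently join two distinct pregnancies.
- Quantiles are type 7; sample (n−1) standard deviations.
- Concepts absent in controls get infinite enrichment fold (kept when the
  person threshold is met); a week value above 44 is rejected as recording
  noise (44 caps the 43-week maximum term).
- All randomness is seeded; two runs from the same configuration are
  byte-identical, and the run manifest contains no timestamps.

## Known limitations

- Term windows and separation minima outside the stated live-birth /
  stillbirth constants are defaults, not method-anchored.
- Registry concept ids and most timing windows are synthetic stand-ins
  (only the estriol 3.75–5.5-month and Polyhydramnios 6–10-month windows
  are anchored); real OMOP concept sets drop in via `load_registry()`.
- The ESD window ignores the ±3.5-day half-week quantization of a GW
  record.
- Visit/observation-period linkage, vocabulary services, and claims-data
  variants are out of scope.

## A worked run

```{r example, eval = FALSE}
library(hipps)
cfg <- sim_config(n_persons = 60, random_seed = 42)
sim <- simulate_cohort(cfg)
res <- hipps_pipeline(sim$events, sim$persons)
table(res$episodes$outcome_category)
table(res$episodes$precision_category)
res$heldout_overlap
```

See the README for the printed output of exactly this run.
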