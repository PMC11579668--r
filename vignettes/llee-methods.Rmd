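---
title: "Methods: simulating local cost-consequences of hypoglycemia-prevention services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating local cost-consequences of hypoglycemia-prevention services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lleesim)
```

## The problem lleesim addresses

Published effectiveness studies of hospital services that prevent
inpatient hypoglycemia rarely transfer directly to another hospital:
the local baseline event rates differ, the studies report effects on
incompatible outcome measures, and local clinicians hold views about how
well an intervention would work in their context. `lleesim` implements a
modeled local-level economic evaluation (LLEE) for this situation. It
simulates an admission-level cohort matching local baseline summaries,
translates published relative risks (RRs) onto a common event-level
measure, applies the effects stochastically event-by-event under
bootstrap resampling, and converts the simulated reductions into a
cost-consequence table: avoided hospital-acquired-complication (HAC)
funding penalties, occupied bed-days, nursing time, and the staff
resources each intervention consumes.

The package deliberately performs a cost-consequence analysis —
disaggregated costs next to a panel of consequences — rather than
collapsing to a cost-per-QALY ratio, because local service decisions are
made on exactly these disaggregated quantities.

## The cohort model

An admission carries cohort flags (adult, obstetric, surgical, ICU), an
integer length of stay, an ordered list of categorized blood-glucose
events, and a coded-HAC flag. Events are categorized, not continuous
glucose traces: severe hypoglycemia (point-of-care BGL < 2.2 mmol/L),
non-severe hypoglycemia (2.2 to < 4.0 mmol/L), and hyperglycemia
(> 15.0 mmol/L). Only categorized events enter the economics, so the
generator never synthesizes glucose time series.

### Events per affected admission

The local baseline is summarized by three numbers: admissions with at
least one hypoglycemia event, total hypoglycemia events, and the share
of affected admissions with two or more events. Matching a mean of
`1732 / 641 = 2.702` events per affected admission together with
`P(>= 2 events) = 0.63` requires a two-parameter zero-truncated count
family; we use the zero-truncated negative binomial (ZTNB). It is the
minimal faithful choice: the truncated Poisson is a one-parameter family
and, at this mean, forces `P(>= 2) = 0.77`; the ZTNB spans
`[0.53, 0.77]` (logarithmic-series limit to Poisson limit), so the
observed 0.63 pins the dispersion. `ztnb_fit()` solves both moments to
`1e-6` with a nested root-finder, and `fit_generator()` wraps this
together with the affected-admission probability.

```{r}
fit <- ztnb_fit(mean = 1732 / 641, p_multi = 0.63)
unlist(fit[c("mu", "size")])
```

### Generator defaults and why

* `n_admissions = 40000`: the eligible population size is not part of
  the baseline summaries; 40,000 annual eligible admissions is a
  realistic figure for a large principal-referral hospital and makes the
  expected affected count 641 at the fitted `p_affected`. It is
  configurable and none of the cost outputs depend on it beyond Monte
  Carlo resolution.
* `severe_share = 0.10`: the baseline severe/non-severe split is not
  published; one in ten hypoglycemia events severe is clinically
  plausible for a general inpatient population and the parameter is
  exposed for sensitivity analysis.
* `hyper_rate = 0.04` events per patient-day: baseline hyperglycemia
  counts could not be estimated from the local data, so this parameter
  has no anchor; 0.04/day gives roughly one in five 5-day admissions a
  recorded hyperglycemia event, enough to exercise the dysglycemia
  reporting criteria without dominating them.
* `los_mean = 5` days, `surgical_share = 0.30`, `icu_share = 0.05`,
  `obstetric_share = 0.05`: typical acute-hospital case-mix values;
  stays are `1 + Poisson(los_mean - 1)` so every stay has at least one
  day.
* Coded HACs are Bernoulli per affected admission at 24.0 %
  (non-surgical) and 25.5 % (surgical), the locally derived coding
  fractions.
* Event days are uniform over the stay by default (day 0 = admission
  day). A `front_loaded` profile (geometric decay, halving every three
  days) is offered because insulin-titration events cluster early; the
  choice only matters for the reporting-criteria logic and the
  patient-day measure.

What the generator does *not* emulate: within-admission correlation of
event severity, seasonal patterns, readmissions, and the audit's
percentage breakdowns of event causes (several of those printed
percentages are mutually inconsistent with their stated denominator and
are not targeted). Passing tests therefore show the pipeline arithmetic
and its statistical behaviour are right under the stated structure, not
that the structure captures every feature of real admissions data.

## The prevention engine

Intervention effects are applied at the event level: for each
hypoglycemia event of an admission in the intervention's target
population, draw `U ~ Uniform(0, 1)` and mark the event prevented iff
`U > RR` for the event's severity channel. Hyperglycemia events are
never prevented. Events within a patient are treated as independent —
the same simplification the evaluation design makes — which likely
*understates* the number of patients whose events are all prevented,
since real within-patient correlation would make full prevention more
common. We document rather than "fix" this.

Where a study published no severe-specific effect, the severe channel
inherits the total-hypoglycemia RR, reflecting the elicitation panel's
stated expectation of equal effects. `RR = 0` is accepted as the
prevent-all boundary for testing, although no published or elicited
value reaches it.

### Reporting criteria

A virtual glycemic management service only reviews patients flagged by
dysglycemia criteria: two or more hyperglycemia events or at least one
hypoglycemia event in the previous 24 hours. The 24-hour window is
approximated by one model day, and eligibility is evaluated per event
against *pre-intervention* history (an event prevented earlier in the
same replicate still counts toward the criteria) — the simplest
self-consistent reading. A consequence worth knowing: an admission's
first-ever event can only be reached if prior hyperglycemia already
triggered the criteria, so under this rule the count of patients with
*all* events prevented is structurally small for criteria-restricted
interventions. An alternative reading — criteria select a patient
cohort whose every event is then in reach — would raise that count; we
keep the per-event rule because it makes the restriction explicit and
testable event-by-event.

Calibration (below) is performed without the criteria restriction and
the restriction is applied in the simulation stage, mirroring how a
published whole-population effect is locally narrowed to the reviewed
cohort.

### Bootstrap

Outputs are stabilized as means over bootstrap replicates (study
default 5,000; tests and examples use hundreds, which is enough for the
quantities asserted because admission-level resampling noise scales as
`1/sqrt(n_boot)`). The resampling unit is the admission with its whole
event list, preserving within-patient clustering. Coded-HAC reductions
are recomputed inside every replicate as the HAC fraction times the
reduction in patients with at least one event, so penalty savings stay
exact multiples of the per-HAC penalty.

## Calibrating heterogeneous outcome measures

The three source studies report effects on three different measures:
hypoglycemic point-of-care measurements (events), patient-days with at
least one event, and patients with at least one event. Event-level RRs
are the common currency. For a unit (admission or patient-day) holding
`k` relevant events, independent event-level prevention retains at
least one event with probability `1 - (1 - r)^k`, so the modeled
patients- or patient-days-measure RR at event-level RR `r` is the mean
of that expression over baseline units. This map is strictly increasing
in `r`, equals 0 at `r = 0` and 1 at `r = 1`, so any published RR in
`(0, 1)` is attainable and bisection on `[0, 1]` converges; with
`max_iter = 60` the bracket closes far below any practical tolerance.
Convergence is declared when the modeled and published RRs differ by at
most 0.001 (the evaluation's stated tolerance). The published RR of 1
maps to event RR 1 exactly — the inverse map is ill-conditioned at the
null, so the endpoints are checked before bisecting. Whenever an
admission holds two or more relevant events the calibrated event-level
RR is strictly below the published patients-measure RR (clustering
inequality).

Two modes exist: `closed_form` (the expectation above) and
`monte_carlo`, which evaluates the modeled RR by bootstrap simulation
with a fixed per-evaluation seed so the objective stays deterministic
for the root-finder. The Monte-Carlo mode exists to show the faithful
simulated loop agrees with the analytic shortcut; on a 500-admission
fixture with 5,000 replicates the two calibrated values agree within
0.002.

When both severe and total RRs are published on the same measure, the
severe channel is calibrated first against severe-event units, then the
non-severe channel is calibrated so the combined all-hypoglycemia
measure matches the total target with the severe channel fixed. The
ordering is an interpretation — the source description treats both
channels but does not state the coupling rule — and is recorded as such;
an infeasible pairing (the total target outside the range reachable with
the severe channel pinned) returns an explicit infeasibility report
rather than a forced answer.

```{r}
two_ev <- cohort(
  data.frame(admission_id = 1:4, adult = TRUE, obstetric = FALSE,
             surgical = FALSE, icu = FALSE, length_of_stay = 2,
             coded_hac = FALSE),
  data.frame(admission_id = rep(1:4, each = 2), day = rep(0:1, 4),
             category = "nonsevere_hypo"))
calibrate(calibration_problem(two_ev, 0.64, measure = "patients"))
```

## Effect-size preprocessing

`rr_from_2x2()` turns raw arm counts into an RR with a Katz log-method
confidence interval — the standard companion to a chi-squared test; the
source material does not name an interval method — and an uncorrected
Pearson chi-squared p-value (a flag enables the Yates correction). A
zero intervention-arm count yields RR 0 with the interval flagged
undefined rather than an error; a zero control-arm count is an error
because the risk ratio itself is undefined. `or_to_rr()` applies the
baseline-risk correction `OR / (1 - p0 + p0 * OR)`.

## Cost-consequence arithmetic

All unit costs live in `cost_params()`: AU$1,132 penalty per coded HAC,
AU$1,450 per occupied bed-day, 3 bed-days avoided per admission with
all events prevented, 5 / 25 nursing minutes per non-severe / severe
event, 1 minute per root-cause survey, and a 38-hour, 52-week FTE.
Two numerical conventions matter:

* The bed-day cost is *adoptable or derivable*: the long-stay outlier
  per-diem price weight times the national efficient price gives
  `0.2641 * 5597 = 1478.17`, but the evaluation adopted AU$1,450 and
  all its printed savings are exact multiples of 1,450. The default is
  therefore 1,450 and `derive_bed_day_cost()` exposes the derivation
  (and the discrepancy) for sensitivity analysis.
* Bootstrap means are rounded to whole units *before* costing, so every
  dollar cell equals quantity times unit cost exactly (penalty savings
  divisible by 1,132, bed-days by 3). Nursing time is kept exact to the
  minute internally; hours are rounded only at render time. Annual
  staff hours truncate (3 × 0.2 FTE × 38 × 52 = 1,185.6 → 1,185
  hours). Unfunded time — nursing minutes absorbed by existing rosters —
  is reported as hours with an opportunity-cost annotation and never
  silently monetized.

The number of completed surveys entering the nursing balance is a free
input (`surveys_completed`): the relation between annual event counts
and surveys actually completed is not fixed by the evaluation, so the
package does not guess it.

## Degenerate inputs and tie-breaks

* `p_affected = 0` produces an event-free cohort whose HAC fraction is
  reported as absent (`NA`), not zero.
* A target mean of exactly 1 event per affected admission collapses the
  count distribution to a point mass; a requested `P(>= 2) > 0` is then
  an explicit infeasibility error, as is any moment pair outside the
  ZTNB's attainable range.
* Within-day event order is the recorded order; the reporting rule's
  history is "earlier in the day-ordered list", so two same-day events
  are asymmetric in the natural way.
* Calibration that exhausts `max_iter` returns `converged = FALSE` with
  its full iteration trace; downstream stages refuse to run on a
  non-converged calibration.

## Problem sizes used by the shipped tests

The test suite and acceptance script run cohorts of 300–40,000
admissions with bootstrap counts between 1 and 5,000, chosen so the
asserted Monte-Carlo bands (2–3 standard errors) are comfortably
resolved; statistical properties asserted at tight bands use scaled-up
cohorts so sampling noise sits well inside the band. The full
study-scale configuration (40,000 admissions, 5,000 replicates per
scenario) runs in minutes and is what `run_pipeline()` defaults to.

## Known limitations

* Independence of events within a patient (understates full
  prevention — see above).
* Bed-day savings accrue only to admissions with *all* events
  prevented; partial prevention plausibly shortens stays too, so the
  bed-day consequence is conservative.
* No time-dependence of effects: alert fatigue and decaying educational
  effects are noted qualitatively, not modeled.
* Hyperglycemia outcomes of interventions are out of scope (no local
  baseline exists to calibrate against), and the baseline
  hyperglycemia rate itself is a judgment-based default.
* The elicited three-point RRs are treated as fixed scenario values;
  published confidence intervals are propagated as separate scenario
  endpoints, not sampled within bootstraps.
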