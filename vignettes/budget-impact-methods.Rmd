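---
title: "Methods: a two-cycle budget impact engine for peripheral drug-eluting stents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-cycle budget impact engine for peripheral drug-eluting stents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stentbim)
```

## The question the model answers

When a hospital system switches from one drug-eluting stent (DES) to
another for superficial femoral artery lesions in symptomatic peripheral
arterial disease, what does it cost — or save — over a multi-year horizon?
`stentbim` answers this with a deterministic cohort budget impact model
(BIM): no patient-level simulation, no sampling, just linear accounting
from trial-observed event rates, a population schedule, and unit costs.

The shipped base case compares Eluvia (a polymer-based paclitaxel-eluting
stent) as intervention against Zilver PTX (a polymer-free
paclitaxel-coated stent) as comparator, for the Australian public system
over six annual cohorts starting in 2019. The budget impact is defined as
the difference between a world in which every treated patient receives the
comparator and one in which every patient receives the intervention.

## Model structure

### Population

Each model year `t` a new cohort of `N_t` patients receives an index stent.
Two routes produce the schedule:

* an **epidemiological funnel** (`funnel_spec()`): a base population is
  multiplied through an ordered chain of fractions (prevalence,
  symptomatic share, lesion location, ...), then by the endovascular
  procedure (EVP) eligibility rate (default 0.80) and the DES use rate
  (default 0.28); later years grow geometrically at a procedure growth
  rate (default 0.068/year, the recent average annual growth of stent
  procedure volumes);
* an **explicit schedule** (`cohort_schedule()`), used by the shipped base
  case: 5674, 6060, 6474, 6915, 7386, 7890 patients (40,399 in total). The
  explicit row is preferred for the fixture because no single constant
  growth rate regenerates it exactly — the implied year-on-year ratios
  drift between 1.0680 and 1.0683, consistent with intermediate rounding
  in the original spreadsheet — and the printed schedule is the quantity
  everything downstream must reproduce.

Populations are kept unrounded internally. Every displayed count is rounded
half away from zero at report time only; totals are rounded from unrounded
sums. This ordering matters: the total of avoided revascularisations is
4198 from the unrounded sum while the rounded per-year cells sum to 4199.

### Events: the two-cycle convention

Each cohort contributes adverse events in exactly two model years and
nothing afterwards:

* **first cycle** (index year): `N_t * r12`, the 12-month cumulative
  clinically driven target-lesion revascularisation (CD-TLR) rate;
* **second cycle** (the following year): `N_{t-1} * r24` under the default
  `cumulative_recount` mode, where `r24` is the 24-month *cumulative* rate.

Major amputations follow the same scheme with `a12`/`a24`, and hospital
bed-days for adverse events use per-patient intensities `h12`/`h24`:
`days_t = N_t * h12 + N_{t-1} * h24`.

`cumulative_recount` deliberately re-applies the full cumulative 24-month
rate to a cohort that was already charged its 12-month events. This
double-counts first-year events — the visible symptom is a marked jump in
events between a cohort's first and second cycle — but it is the
convention the published Australian analysis uses, and it is the unique
convention under which the engine reproduces that analysis cell-by-cell.
The package therefore defaults to it and also offers an `incremental` mode
charging only `r24 - r12` in the second cycle, which is the
epidemiologically cleaner reading. Incremental totals never exceed recount
totals; the gap is exactly `sum(N_{t-1}) * r12`, so the two modes coincide
only when the 12-month rate is zero.

A related convention choice is *which numeric form of the rates to use*.
The source trial reports 12-month rates as explicit fractions (13/287
Eluvia, 13/145 Zilver PTX) and 24-month rates only as one-decimal
percentages (12.7%, 20.1%). The fixture stores 12-month rates as the exact
fractions and 24-month rates as the printed percentages, because
brute-force reconstruction shows this mixed convention is the only one
that reproduces every CD-TLR cell of the published table. The source never
states this; it is reverse-engineered, and `arm_parameters()` accepts any
convention for other applications.

### Hospital-day intensities and their calibration

The per-patient day intensities `h12`/`h24` are not reported anywhere as
such. They are, however, implicit in the published per-year hospital-system
expenditures, which equal `days * c_bed_day`. `calibrate_day_intensities()`
inverts the two-cycle day formula on the first two years:

```
h12 = D0 / N0
h24 = (D1 - N1 * h12) / N0
```

The fixture sets `D0`, `D1` per arm to the published year-0/year-1
hospital-cost cells divided by the per-diem ($2003), because the cost
cells carry more significant digits than the rounded day counts —
calibrating from the rounded day cells instead shifts the year-5
prediction by about a day. The calibration then *predicts* years 2–5; that
these out-of-sample cells match the published table to the nearest day is
the strongest internal check that the day model is the one actually used.

The trial's hospitalisation summary statistics (13.9 vs 17.7 days for
adverse events per admitted patient at 12 months, implying average stays
of 5.5 vs 6.8 days and a 19% relative reduction) are carried as metadata
via `average_stay_reduction()` but are deliberately *not* the source of
`h12`/`h24`: no published arithmetic connects them to the day totals.

### Costs and the two perspectives

Unit costs (AUD): percutaneous TLR $5495, open surgical TLR $16,411, major
amputation $35,354, hospital bed-day $2003. TLR events are split
percutaneous/open by cycle-specific mixes before costing.

* **Healthcare-system perspective** (activity-based funding): index
  procedures at `c_primary` plus the stent price, plus TLR and amputation
  tariffs. The index-procedure payment is not published (it sits in
  unpublished diagnosis-related-group cost weights); the fixture sets it
  to the percutaneous tariff ($5495, same DRG family) and flags the
  absolute cost rows as non-calibrated. Crucially, `c_primary` and any
  equal stent price cancel *exactly* in the between-arm difference, so
  this choice cannot affect any savings figure. The absolute
  healthcare-system cost rows (and hence the published $12.1M headline
  savings from that perspective) are not reproducible from the published
  unit costs alone — the closest reconstruction of the year-0 saving is
  about $932k against a printed $939,538 — so that path is validated by
  structural properties (cancellation, antisymmetry, linearity,
  monotonicity) rather than cell values.
* **Hospital perspective**: bed-days times the per-diem, nothing else. It
  ignores all procedure tariffs and stent prices by construction, and is
  exactly linear in `c_bed_day`. This perspective reproduces the published
  cells to within the sub-dollar rounding of the printed inputs.

### Scenarios and state disaggregation

The entire engine is homogeneous of degree 1 in the cohort schedule, so
population scenarios (EVP eligibility 0.70–0.99, DES use 0.10–0.40) are
applied as exact multiplicative factors `new_rate / base_rate` on the
schedule — provably identical to re-running the funnel. Price scenarios
(stent price and per-diem, ±5–10%) multiply the respective unit costs.
Bounds are validated; a configuration can relax them to warnings for
exploratory sweeps, since published scenario analyses do probe beyond base
assumptions.

State/territory results are the national unrounded quantities times
per-state shares. The default shares are back-calculated from published
state cohort counts at the base use rate divided by the national total
(40,399); they intentionally sum to about 0.984 — the published state
cohorts leave roughly 1.6% of the national cohort unallocated, and the
engine preserves that rather than renormalising.

## The synthetic-data generator

`simulate_trial()` emulates the statistical structure of a two-arm device
trial: 12-month event counts are binomial at the true rates, and 24-month
counts add a conditional binomial among event-free patients, so observed
cumulative rates are monotone by construction and always pass validation.
Procedure mixes are binomial fractions of observed events.
`simulate_observed_days()` adds Gaussian noise (truncated at zero) to the
exact per-year day totals; the noise is continuous rather than count-based
because the modelled day totals are derived continuous quantities, not
integer admissions. Each generator draws from its own named stream derived
from the single master seed, so adding a generator never perturbs another.

What passing the synthetic suites shows: the projection arithmetic, its
linearity, and the calibration's algebraic inverse (exact recovery at zero
noise; mean `h12` recovery error well below 0.01 days/patient at a
50-day noise SD over 200 replicates, consistent with the `sd/N0`
standard-error scaling). What it does not show: anything about
between-trial heterogeneity, non-binomial event clustering, competing
mortality risk, or more than one revascularisation per patient — all of
which the deterministic model itself excludes by design.

## Numerical choices

* Internal arithmetic is double precision and unrounded end-to-end;
  display rounding is half away from zero (`round_half_up()`), applied
  last.
* Configurations serialize to YAML with `%.17g` formatting, so
  `load_config(save_config(x))` is bit-identical; the schema is strict
  (unknown keys rejected, every invariant re-checked on load).
* Validation tolerances: procedure mixes must sum to 1 within 1e-9;
  cumulative 24-month rates must be at least the 12-month rates under the
  recount mode.
* Degenerate inputs: zero rates give zero projections; a second observed
  year fully explained by the first cycle calibrates to `h24 = 0`; a
  negative calibrated `h24` warns (inconsistent inputs) rather than
  erroring, since the algebra is still well-defined.

Problem sizes throughout the package are desk-scale: six-year horizons,
closed-form projections, 200-replicate Monte Carlo checks — the full test
suite and the reproduction script each run in seconds.

## Known limitations

* No mortality, no competing risks, at most one TLR per patient, no
  projection beyond 24 months per cohort — inherited from the source
  model's scope.
* Absolute healthcare-system cost levels depend on an unpublished
  index-procedure cost weight; only between-arm differences are
  identified.
* No discounting, no currency conversion, no private-payer perspective,
  and no probabilistic sensitivity analysis (the model is
  deterministic-only; one-way sweeps are the supported uncertainty tool).
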