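# stentbim

A deterministic, config-driven **budget impact model (BIM)** for comparing
two drug-eluting stents (DES) in symptomatic lower-limb peripheral arterial
disease. Written for health-economics analysts and hospital payers who need
a tested, reproducible engine rather than a spreadsheet: every number is
recomputed from a declarative YAML configuration, internal arithmetic is
unrounded end-to-end, and the whole pipeline is covered by unit, property
and end-to-end tests.

## The model

For annual treated cohorts `N_0 … N_{T-1}`, each cohort incurs adverse
events in exactly two model years (the *two-cycle convention*):

```
TLR_t  = N_t · r12 + N_{t-1} · r24          (cumulative recount mode)
AMP_t  = N_t · a12 + N_{t-1} · a24
DAYS_t = N_t · h12 + N_{t-1} · h24,         N_{-1} = 0
```

where `r12`, `r24` are 12- and 24-month cumulative clinically driven
target-lesion revascularisation (CD-TLR) rates, `a12`, `a24` amputation
rates, and `h12`, `h24` per-patient hospital bed-day intensities for
adverse events (calibratable from two observed years with
`calibrate_day_intensities()`). Costs are computed from two perspectives —
activity-based funding (procedure tariffs) and hospital bed-days
(`DAYS_t · c_bed_day`) — and the budget impact is the element-wise
difference comparator − intervention. The engine is linear (homogeneous of
degree 1) in the cohort schedule, which makes population scenarios and
state-level disaggregation exact multiplicative scalings.

The shipped fixture (`imperial_au_2019.yaml`) encodes the Australian base
case: Eluvia vs Zilver PTX, two-year trial outcome rates, AUD unit costs,
and the six-year national cohort schedule 2019–2024.

## Worked example

```r
library(stentbim)

fit <- run_bim(load_config(imperial_config_path()))
print(fit)
#> Budget impact model (6 years, mode cumulative_recount)
#>   treated patients: 40,399
#>   zilver_ptx vs eluvia:
#>     TLRs avoided:       4198
#>     bed-days averted:   46,243
#>     healthcare savings: $9,948,283
#>     hospital savings:   $92,624,882
```

Over six years, switching the national treated population from the
comparator to the intervention stent avoids 4198 revascularisations and
frees 46,243 hospital bed-days, worth about $92.6M to hospitals at the
$2003 per-diem. (The healthcare-system savings line depends only on
published procedure tariffs and cancels all unpublished index-procedure
weights; see the methods vignette for why its absolute level is the one
quantity the published unit costs do not pin down.)

Scenario and state views:

```r
run_scenario(load_config(imperial_config_path()),
             scenario_spec("low_use", des_use_rate = 0.10))$totals$days_averted
#> [1] 16515.38   # displays 16,515

render_state_table(fit)[1, c("state", "days_averted")]
#>       state days_averted
#> 1 NSW & ACT 5469–15,312
```

A thin command-line interface over the same functions ships in
`inst/cli/stentbim.R` (`run`, `scenarios`, `states`, `simulate`
subcommands; byte-identical outputs for identical inputs).

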