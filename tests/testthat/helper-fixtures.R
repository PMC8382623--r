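## Frozen display-rounded cells of the published national results table,
## used across test files. Totals are rounded from unrounded sums.
published <- list(
  cohorts = c(5674, 6060, 6474, 6915, 7386, 7890),
  tlr_zilver = c(509, 1684, 1798, 1921, 2052, 2192), tlr_zilver_total = 10156,
  tlr_eluvia = c(257, 995, 1063, 1135, 1213, 1295), tlr_eluvia_total = 5959,
  tlr_avoided = c(252, 689, 736, 786, 839, 897),    tlr_avoided_total = 4198,
  days_zilver = c(7082, 23327, 24917, 26617, 28430, 30368),
  days_zilver_total = 140741,
  days_eluvia = c(3063, 15958, 17045, 18209, 19449, 20774),
  days_eluvia_total = 94498,
  days_averted_total = 46243,
  hosp_cost_zilver_y01 = c(14184422, 46724823),
  hosp_cost_eluvia_y01 = c(6134905, 31964449),
  hosp_savings_y0 = 8049517,
  hosp_savings_total = 92624879
)

## Small fast hand-built config for unit tests that do not need the fixture.
toy_config <- function(n_years = 4) {
  a <- arm_parameters("comp", r12 = 0.10, r24 = 0.20,
                      m12_perc = 0.9, m12_open = 0.1,
                      m24_perc = 0.8, m24_open = 0.2,
                      a12 = 0.01, a24 = 0.02, h12 = 1.5, h24 = 2.5,
                      stent_price = 1000)
  b <- arm_parameters("intv", r12 = 0.05, r24 = 0.12,
                      m12_perc = 0.95, m12_open = 0.05,
                      m24_perc = 0.9, m24_open = 0.1,
                      a12 = 0.005, a24 = 0.01, h12 = 0.8, h24 = 1.9,
                      stent_price = 1000)
  model_config(a, b,
               cost_schedule(5000, 15000, 30000, 2000, c_primary = 6000),
               cohort_schedule(1000 * 1.05^(0:(n_years - 1))))
}
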