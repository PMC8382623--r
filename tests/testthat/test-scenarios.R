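cfg <- default_imperial_config()
base <- run_bim(cfg)$impact

test_that("low device-use scenario scales the national results linearly", {
  res <- run_scenario(cfg, scenario_spec("des10", des_use_rate = 0.10))
  expect_equal(round_half_up(res$totals$tlr_avoided), 1499)
  expect_equal(round_half_up(res$totals$days_averted), 16515)
  expect_equal(res$totals$tlr_avoided, base$totals$tlr_avoided * 10 / 28,
               tolerance = 1e-12)
  ## population row
  m <- attr(res, "model")
  expect_equal(round_half_up(sum(m$cohorts$N)), 14428)
})

test_that("scenario outputs are exactly phi times the base outputs", {
  res <- run_scenario(cfg, scenario_spec("half", cohort_factor = 0.5))
  for (fld in names(base$totals))
    expect_equal(res$totals[[fld]], 0.5 * base$totals[[fld]],
                 tolerance = 1e-12)
  ## base-case spec returns the base result
  same <- run_scenario(cfg, scenario_spec("base"))
  expect_equal(same$totals, base$totals, tolerance = 0)
})

test_that("equal stent-price changes leave both savings unchanged", {
  res <- run_scenario(cfg, scenario_spec("price_up",
                                         stent_price_multiplier_a = 1.10,
                                         stent_price_multiplier_b = 1.10))
  expect_equal(res$totals$hospital_savings, base$totals$hospital_savings)
  expect_equal(res$totals$healthcare_savings, base$totals$healthcare_savings)
})

test_that("out-of-bounds overrides error naming the bound", {
  expect_error(run_scenario(cfg, scenario_spec("bad", des_use_rate = 0.5)),
               "des_use_rate.*0\\.1.*0\\.4")
  expect_error(run_scenario(cfg, scenario_spec("bad", evp_eligibility = 0.5)),
               "evp_eligibility")
  expect_error(run_scenario(cfg, scenario_spec("bad",
                                               bed_day_multiplier = 1.5)),
               "bed_day_multiplier")
  ## relaxed configs warn instead
  c2 <- cfg; c2$enforce_scenario_bounds <- FALSE
  expect_warning(run_scenario(c2, scenario_spec("explore",
                                                des_use_rate = 0.5)),
                 "des_use_rate")
})

test_that("sweeps return one ordered row per scenario plus deltas", {
  tab <- sweep_scenarios(cfg, list(
    scenario_spec("base"),
    scenario_spec("des10", des_use_rate = 0.10),
    scenario_spec("des40", des_use_rate = 0.40)))
  expect_equal(tab$scenario, c("base", "des10", "des40"))
  expect_equal(tab$hospital_savings[3],
               base$totals$hospital_savings * 40 / 28, tolerance = 1e-12)
  expect_equal(tab$delta_hospital_savings[1], 0)
  ## per-diem +5% moves only the hospital-perspective row
  tab2 <- sweep_scenarios(cfg, list(scenario_spec("pd", bed_day_multiplier = 1.05)))
  expect_equal(tab2$hospital_savings, base$totals$hospital_savings * 1.05,
               tolerance = 1e-12)
  expect_equal(tab2$healthcare_savings, base$totals$healthcare_savings,
               tolerance = 1e-12)
  ## empty and duplicate inputs
  expect_equal(nrow(sweep_scenarios(cfg, list())), 0)
  expect_error(sweep_scenarios(cfg, list(scenario_spec("x"),
                                         scenario_spec("x"))),
               "duplicate")
})

test_that("state disaggregation scales every quantity by the share", {
  states <- disaggregate(base)
  nsw <- states[["NSW & ACT"]]
  share <- 13377 / 40399
  expect_equal(round_half_up(nsw$totals$days_averted), 15312)
  expect_equal(nsw$totals$hospital_savings,
               base$totals$hospital_savings * share, tolerance = 1e-12)
  ## low end of the use-rate range
  expect_equal(round_half_up(nsw$totals$days_averted * 10 / 28), 5469)
  ## share 1 recovers the national result
  one <- disaggregate(base, state_partition(c(ALL = 1)))$ALL
  expect_equal(one$totals, base$totals, tolerance = 0)
  expect_error(disaggregate(base, states = "XYZ"), "unknown state")
})

test_that("states sum to national times total allocated share", {
  states <- disaggregate(base)
  total_share <- sum(default_state_shares())
  expect_lt(total_share, 1)  # part of the national cohort is unallocated
  for (fld in names(base$totals)) {
    s <- sum(vapply(states, function(x) x$totals[[fld]], numeric(1)))
    expect_equal(s, base$totals[[fld]] * total_share, tolerance = 1e-9)
  }
  expect_error(state_partition(c(A = 0.7, B = 0.6)), "at most 1")
})
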