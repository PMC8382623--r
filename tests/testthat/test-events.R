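cfg <- default_imperial_config()
cohorts <- cohort_schedule(published$cohorts)

test_that("two-cycle projection reproduces the published CD-TLR cells", {
  pz <- project_events(cohorts, cfg$arm_a)
  pe <- project_events(cohorts, cfg$arm_b)
  ## hand-computed first cells (oracle: direct arithmetic)
  expect_equal(pz$rows$tlr_total[1], 5674 * 13 / 145)          # 508.66
  expect_equal(pz$rows$tlr_total[2], 6060 * 13 / 145 + 5674 * 0.201)
  expect_equal(round_half_up(pz$rows$tlr_total), published$tlr_zilver)
  expect_equal(round_half_up(pe$rows$tlr_total), published$tlr_eluvia)
  expect_equal(round_half_up(pz$totals$tlr_total), published$tlr_zilver_total)
  expect_equal(round_half_up(pe$totals$tlr_total), published$tlr_eluvia_total)
  expect_equal(pe$totals$tlr_total, 5958.56, tolerance = 1e-5)
  ## totals are exact sums of rows
  expect_identical(pz$totals$tlr_total, sum(pz$rows$tlr_total))
  expect_identical(pz$rows$tlr_total,
                   pz$rows$tlr_first_cycle + pz$rows$tlr_second_cycle)
})

test_that("degenerate and invalid projections behave", {
  zero <- arm_parameters("none", 0, 0, 1, 0, 1, 0, 0, 0, h12 = 0, h24 = 0)
  p <- project_events(cohorts, zero)
  expect_true(all(unlist(p$totals) == 0))
  expect_error(project_events(list(N = 1:3), cfg$arm_a), "cohort_schedule")
})

test_that("incremental mode never exceeds cumulative, equal iff r24 == r12", {
  for (seed in 1:8) {
    rc <- random_config(seed)
    s <- stentbim:::resolve_population(rc)
    cum <- project_events(s, rc$arm_a, mode = "cumulative_recount")
    inc <- project_events(s, rc$arm_a, mode = "incremental")
    expect_true(all(inc$rows$tlr_total <= cum$rows$tlr_total + 1e-12))
    expect_lte(inc$totals$tlr_total, cum$totals$tlr_total + 1e-12)
  }
  flat <- arm_parameters("flat", r12 = 0.1, r24 = 0.1, m12_perc = 1,
                         m12_open = 0, m24_perc = 1, m24_open = 0,
                         a12 = 0.01, a24 = 0.01, h12 = 1, h24 = 1)
  cum <- project_events(cohorts, flat, mode = "cumulative_recount")
  inc <- project_events(cohorts, flat, mode = "incremental")
  expect_equal(cum$rows$tlr_total - inc$rows$tlr_total,
               c(0, published$cohorts[-6]) * 0.1)  # double-count = N_{t-1} r12
  expect_gt(cum$totals$tlr_total, inc$totals$tlr_total)
})

test_that("projections are homogeneous of degree 1 in the schedule", {
  p1 <- project_events(cohorts, cfg$arm_a)
  p2 <- project_events(scale_schedule(cohorts, 2.5), cfg$arm_a)
  for (f in names(p1$totals))
    expect_equal(p2$totals[[f]], 2.5 * p1$totals[[f]], tolerance = 1e-12)
})

test_that("procedure split preserves totals and honours degenerate mixes", {
  pz <- project_events(cohorts, cfg$arm_a)
  sp <- split_tlr_by_procedure(pz$rows$tlr_first_cycle,
                               pz$rows$tlr_second_cycle, cfg$arm_a)
  expect_equal(sp$perc[1], 5674 * 13 / 145 * 0.96)   # 488.3
  expect_equal(sp$open[1], 5674 * 13 / 145 * 0.04)   # 20.3
  expect_equal(sp$perc + sp$open, pz$rows$tlr_total, tolerance = 1e-12)
  allp <- arm_parameters("p", 0.1, 0.2, 1, 0, 1, 0, 0, 0)
  sp2 <- split_tlr_by_procedure(c(3, 4), c(1, 2), allp)
  expect_equal(sp2$perc, c(4, 6))
  expect_equal(sp2$open, c(0, 0))
  ## conservation on random inputs
  set.seed(42)
  for (i in 1:10) {
    t1 <- runif(6, 0, 100); t2 <- runif(6, 0, 100)
    sp3 <- split_tlr_by_procedure(t1, t2, cfg$arm_b)
    expect_equal(sp3$perc + sp3$open, t1 + t2, tolerance = 1e-12)
  }
})

test_that("day-intensity calibration matches the back-solve oracle", {
  ## oracle computed by direct division on the published year-0/1 cells
  h <- calibrate_day_intensities(5674, 6060, 14184422 / 2003,
                                 46724823 / 2003)
  expect_equal(h$h12, 1.248077, tolerance = 1e-6)
  expect_equal(h$h24, 2.778300, tolerance = 1e-6)
  he <- calibrate_day_intensities(5674, 6060, 6134905 / 2003,
                                  31964449 / 2003)
  expect_equal(he$h12, 0.539806, tolerance = 1e-6)
  expect_equal(he$h24, 2.236000, tolerance = 1e-6)
  ## degenerate: second year fully explained by first cycle
  expect_equal(calibrate_day_intensities(100, 50, 200, 100)$h24, 0)
  expect_error(calibrate_day_intensities(0, 50, 10, 10), "N0")
  expect_warning(calibrate_day_intensities(100, 50, 200, 50), "negative")
})

test_that("calibrated intensities reproduce and extrapolate the day cells", {
  pz <- project_events(cohorts, cfg$arm_a)
  pe <- project_events(cohorts, cfg$arm_b)
  ## exact round-trip of the calibration years
  expect_equal(pz$rows$hospital_days_total[1:2],
               published$hosp_cost_zilver_y01 / 2003, tolerance = 1e-12)
  expect_equal(pe$rows$hospital_days_total[1:2],
               published$hosp_cost_eluvia_y01 / 2003, tolerance = 1e-12)
  ## years 2-5 predicted to the nearest day
  expect_equal(round_half_up(pz$rows$hospital_days_total),
               published$days_zilver)
  expect_equal(round_half_up(pe$rows$hospital_days_total),
               published$days_eluvia)
  expect_equal(round_half_up(pz$totals$hospital_days_total),
               published$days_zilver_total)
  expect_equal(round_half_up(pe$totals$hospital_days_total),
               published$days_eluvia_total)
})

test_that("trial stay metadata yields the reported 19% stay reduction", {
  s <- average_stay_reduction()
  expect_equal(s$stay_b, 13.9 * 123 / 309)   # 5.5 days
  expect_equal(s$stay_a, 17.7 * 60 / 156)    # 6.8 days
  expect_equal(round_half_up(s$reduction, 2), 0.19)
})
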