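test_that("default base case stores 12-month rates as exact trial fractions", {
  cfg <- default_imperial_config()
  expect_identical(cfg$arm_a$r12, 13 / 145)
  expect_identical(cfg$arm_b$r12, 13 / 287)
  expect_identical(cfg$arm_b$a12, 1 / 287)
  expect_identical(cfg$arm_a$a12, 0)
  ## 24-month rates are the reported one-decimal percentages
  expect_identical(cfg$arm_a$r24, 0.201)
  expect_identical(cfg$arm_b$r24, 0.127)
  expect_identical(cfg$arm_a$a24, 0.007)
  expect_identical(cfg$arm_b$a24, 0.015)
})

test_that("default base case carries the published costs, mixes and cohorts", {
  cfg <- default_imperial_config()
  expect_equal(cfg$costs$c_percutaneous, 5495)
  expect_equal(cfg$costs$c_open, 16411)
  expect_equal(cfg$costs$c_amputation, 35354)
  expect_equal(cfg$costs$c_bed_day, 2003)
  expect_equal(cfg$arm_a$m12_perc, 0.96)
  expect_equal(cfg$arm_b$m12_perc, 0.967)
  expect_equal(cfg$arm_a$m24_perc, 0.971)
  expect_equal(cfg$arm_b$m24_perc, 0.957)
  expect_equal(cfg$population$N, published$cohorts)
  ## equal stent prices: the price difference contributes nothing
  expect_equal(cfg$arm_a$stent_price, cfg$arm_b$stent_price)
})

test_that("default day intensities equal the two-year back-solve oracle", {
  cfg <- default_imperial_config()
  ## independent oracle: direct division on the published year-0/1 cells
  D0z <- 14184422 / 2003; D1z <- 46724823 / 2003
  h12z <- D0z / 5674
  h24z <- (D1z - 6060 * h12z) / 5674
  expect_equal(cfg$arm_a$h12, h12z, tolerance = 1e-12)
  expect_equal(cfg$arm_a$h24, h24z, tolerance = 1e-12)
  D0e <- 6134905 / 2003; D1e <- 31964449 / 2003
  h12e <- D0e / 5674
  expect_equal(cfg$arm_b$h12, h12e, tolerance = 1e-12)
  expect_equal(cfg$arm_b$h24, (D1e - 6060 * h12e) / 5674, tolerance = 1e-12)
  expect_equal(cfg$arm_b$h24, 2.236, tolerance = 1e-6)
})

test_that("arm validation rejects each invariant violation", {
  ok <- function(...) arm_parameters("x", r12 = 0.1, r24 = 0.2,
                                     m12_perc = 0.9, m12_open = 0.1,
                                     m24_perc = 0.9, m24_open = 0.1,
                                     a12 = 0.01, a24 = 0.02, ...)
  expect_s3_class(ok(), "arm_parameters")
  bad <- function(field, value) {
    a <- ok(); a[[field]] <- value
    expect_error(validate_arm_parameters(a))
  }
  bad("r12", -0.1); bad("r24", 1.2)
  bad("m12_perc", 0.5)                       # mix no longer sums to 1
  bad("h12", -1); bad("stent_price", -5)
  a <- ok(); a$r24 <- 0.05                   # r24 < r12 under cumulative
  expect_error(validate_arm_parameters(a), "r24")
  expect_silent(validate_arm_parameters(a, cumulative = FALSE))
})

test_that("config serialization round-trips losslessly", {
  cfg <- default_imperial_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)
  expect_identical(load_config(path), cfg)
  ## state shares (awkward fractions) preserved exactly
  expect_identical(load_config(path)$state_shares, cfg$state_shares)
  ## random configs round-trip too
  for (seed in 1:5) {
    rc <- random_config(seed)
    save_config(rc, path)
    expect_identical(load_config(path), rc)
  }
})

test_that("shipped fixture equals the programmatic default", {
  expect_equal(load_config(imperial_config_path()), default_imperial_config())
})

test_that("load_config enforces the strict schema", {
  cfg <- default_imperial_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, path)

  mangle <- function(f) {
    l <- yaml::read_yaml(path)
    l <- f(l)
    p2 <- tempfile(fileext = ".yaml")
    writeLines(yaml::as.yaml(l), p2)
    p2
  }
  ## unknown key rejected
  expect_error(load_config(mangle(function(l) { l$bogus <- 1; l })),
               "unknown key")
  ## missing required field named in the error
  expect_error(load_config(mangle(function(l) { l$arm_a$r12 <- NULL; l })),
               "r12")
  ## rate outside [0,1]
  expect_error(load_config(mangle(function(l) { l$arm_a$r24 <- 1.5; l })),
               "r24")
  ## mix not summing to 1
  expect_error(load_config(mangle(function(l) {
    l$arm_a$m12_perc <- 0.5; l$arm_a$m12_open <- 0.4; l })),
    "m12")
  ## r24 < r12 under cumulative recount
  expect_error(load_config(mangle(function(l) { l$arm_a$r24 <- 0.01; l })),
               "r24")
})

test_that("save_config fails cleanly on unwritable paths", {
  cfg <- default_imperial_config()
  expect_error(save_config(cfg, ""), "path")
  expect_error(save_config(cfg, file.path(tempdir(), "no", "such", "dir",
                                          "x.yaml")))
  expect_error(load_config(file.path(tempdir(), "absent.yaml")), "not found")
})
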