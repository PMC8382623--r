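#' Clinical and resource-use parameters for one stent arm
#'
#' Bundles everything the projection needs about one device arm: cumulative
#' clinically driven target-lesion revascularisation (CD-TLR) rates at 12 and
#' 24 months, the percutaneous/open procedure mix at each time point,
#' cumulative major-amputation rates, per-patient hospital bed-day
#' intensities for adverse events in the first and second model cycle, and
#' the per-unit stent price added to the index procedure.
#'
#' Twelve-month rates should be supplied as exact trial fractions (e.g.
#' `13/287`), not their rounded percentages; 24-month rates follow whatever
#' convention the source reports. Under the default cumulative second-cycle
#' convention `r24` must be at least `r12`.
#'
#' @param arm_name label for the arm (e.g. `"zilver_ptx"`).
#' @param r12,r24 cumulative CD-TLR rates at 12 and 24 months (fractions).
#' @param m12_perc,m12_open percutaneous/open split of 12-month TLRs; must
#'   sum to 1.
#' @param m24_perc,m24_open percutaneous/open split of 24-month TLRs.
#' @param a12,a24 cumulative major-amputation rates at 12 and 24 months.
#' @param h12 hospital bed-days for adverse events per treated patient,
#'   applied in a cohort's index year (days/patient).
#' @param h24 cumulative bed-days per treated patient applied in a cohort's
#'   second year (days/patient).
#' @param stent_price additive per-patient index stent cost (AUD).
#' @return an object of class `arm_parameters`.
#' @seealso [default_imperial_config()], [calibrate_day_intensities()]
#' @export
arm_parameters <- function(arm_name, r12, r24, m12_perc, m12_open,
                           m24_perc, m24_open, a12, a24,
                           h12 = 0, h24 = 0, stent_price = 0) {
  x <- structure(list(
    arm_name = as.character(arm_name),
    r12 = r12, r24 = r24,
    m12_perc = m12_perc, m12_open = m12_open,
    m24_perc = m24_perc, m24_open = m24_open,
    a12 = a12, a24 = a24,
    h12 = h12, h24 = h24,
    stent_price = stent_price
  ), class = "arm_parameters")
  validate_arm_parameters(x)
  x
}

validate_arm_parameters <- function(x, cumulative = TRUE) {
  nm <- x$arm_name
  for (f in c("r12", "r24", "m12_perc", "m12_open", "m24_perc", "m24_open",
              "a12", "a24"))
    check_fraction(x[[f]], paste0(nm, ".", f))
  for (f in c("h12", "h24", "stent_price"))
    check_nonneg(x[[f]], paste0(nm, ".", f))
  if (abs(x$m12_perc + x$m12_open - 1) > 1e-9)
    stop_bim(sprintf("`%s`: m12_perc + m12_open must equal 1 (got %.10g)",
                     nm, x$m12_perc + x$m12_open))
  if (abs(x$m24_perc + x$m24_open - 1) > 1e-9)
    stop_bim(sprintf("`%s`: m24_perc + m24_open must equal 1 (got %.10g)",
                     nm, x$m24_perc + x$m24_open))
  if (cumulative && x$r24 < x$r12)
    stop_bim(sprintf(
      "`%s`: r24 (%.6g) < r12 (%.6g) is inconsistent with cumulative rates",
      nm, x$r24, x$r12))
  if (cumulative && x$a24 < x$a12)
    stop_bim(sprintf(
      "`%s`: a24 (%.6g) < a12 (%.6g) is inconsistent with cumulative rates",
      nm, x$a24, x$a12))
  invisible(x)
}

#' Unit costs applied to projected events
#'
#' All values in Australian dollars. `c_primary` prices the index procedure
#' itself (excluding the stent); it cancels exactly in every between-arm
#' difference, so its absolute level only affects absolute per-arm cost rows.
#'
#' @param c_percutaneous cost of a percutaneous endovascular TLR.
#' @param c_open cost of an open surgical TLR.
#' @param c_amputation cost of a major amputation.
#' @param c_bed_day national weighted average cost per hospital bed-day.
#' @param c_primary activity-based-funding payment for the index procedure.
#' @return an object of class `cost_schedule`.
#' @export
cost_schedule <- function(c_percutaneous, c_open, c_amputation, c_bed_day,
                          c_primary = 0) {
  x <- structure(list(
    c_percutaneous = c_percutaneous, c_open = c_open,
    c_amputation = c_amputation, c_bed_day = c_bed_day,
    c_primary = c_primary
  ), class = "cost_schedule")
  for (f in names(unclass(x))) check_nonneg(x[[f]], f)
  x
}

#' Default bounds for one-way scenario parameters
#'
#' Eligibility for endovascular procedures may move between 70% and 99%,
#' device use between 10% and 40%, and stent prices and the bed-day cost by
#' up to 10% either way.
#'
#' @return named list of length-2 numeric bounds.
#' @export
default_scenario_ranges <- function() {
  list(
    evp_eligibility      = c(0.70, 0.99),
    des_use_rate         = c(0.10, 0.40),
    stent_price_multiplier = c(0.90, 1.10),
    bed_day_multiplier     = c(0.90, 1.10),
    cohort_factor          = c(0, Inf)
  )
}

#' Assemble a full model configuration
#'
#' One `model_config` is one complete model: two device arms, a cost
#' schedule, a population (either an explicit [cohort_schedule()] or a
#' [funnel_spec()] to derive one), the horizon, the second-cycle accounting
#' mode, optional state shares for subnational disaggregation, and the
#' scenario bounds.
#'
#' @param arm_a comparator [arm_parameters()] (costs are differenced as
#'   `arm_a - arm_b`, so savings are positive when `arm_b` performs better).
#' @param arm_b intervention [arm_parameters()].
#' @param costs a [cost_schedule()].
#' @param population a [cohort_schedule()] or a [funnel_spec()].
#' @param n_years number of model years (cohorts). Defaults to the length of
#'   an explicit schedule or the funnel's `n_years`.
#' @param second_cycle_mode `"cumulative_recount"` (default) applies the
#'   full cumulative 24-month rate to the prior year's cohort;
#'   `"incremental"` applies only the 12-to-24-month increment `r24 - r12`.
#' @param state_shares optional named fractions of the national cohort per
#'   state/territory; need not sum to 1.
#' @param scenario_ranges bounds for scenario overrides; see
#'   [default_scenario_ranges()].
#' @param enforce_scenario_bounds if `FALSE`, out-of-range scenario
#'   overrides warn instead of erroring (exploratory sweeps).
#' @return an object of class `model_config`.
#' @export
model_config <- function(arm_a, arm_b, costs, population,
                         n_years = NULL,
                         second_cycle_mode = c("cumulative_recount",
                                               "incremental"),
                         state_shares = NULL,
                         scenario_ranges = default_scenario_ranges(),
                         enforce_scenario_bounds = TRUE) {
  second_cycle_mode <- match.arg(second_cycle_mode)
  if (!inherits(arm_a, "arm_parameters") || !inherits(arm_b, "arm_parameters"))
    stop_bim("`arm_a` and `arm_b` must be arm_parameters objects")
  if (!inherits(costs, "cost_schedule"))
    stop_bim("`costs` must be a cost_schedule object")
  if (!inherits(population, "cohort_schedule") &&
      !inherits(population, "funnel_spec"))
    stop_bim("`population` must be a cohort_schedule or a funnel_spec")
  if (is.null(n_years)) {
    n_years <- if (inherits(population, "cohort_schedule"))
      length(population$N) else population$n_years
  }
  if (!is.numeric(n_years) || n_years < 1)
    stop_bim("`n_years` must be at least 1")
  cumulative <- second_cycle_mode == "cumulative_recount"
  validate_arm_parameters(arm_a, cumulative = cumulative)
  validate_arm_parameters(arm_b, cumulative = cumulative)
  if (!is.null(state_shares)) {
    if (is.null(names(state_shares)) || any(names(state_shares) == ""))
      stop_bim("`state_shares` must be a named vector/list")
    state_shares <- unlist(state_shares)
    for (s in names(state_shares))
      check_fraction(state_shares[[s]], paste0("state_shares.", s))
    if (sum(state_shares) > 1 + 1e-9)
      stop_bim("`state_shares` must sum to at most 1")
  }
  structure(list(
    arm_a = arm_a, arm_b = arm_b, costs = costs,
    population = population, n_years = as.integer(n_years),
    second_cycle_mode = second_cycle_mode,
    state_shares = state_shares,
    scenario_ranges = scenario_ranges,
    enforce_scenario_bounds = isTRUE(enforce_scenario_bounds)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  pop <- if (inherits(x$population, "cohort_schedule"))
    sprintf("explicit schedule, %d years, total %s patients",
            length(x$population$N), fmt_int(sum(x$population$N)))
  else
    sprintf("funnel (base %s, EVP %.0f%%, device use %.0f%%), %d years",
            fmt_int(x$population$base_population),
            100 * x$population$evp_eligibility,
            100 * x$population$des_use_rate, x$population$n_years)
  cat("Budget impact model configuration\n")
  cat(sprintf("  comparator:   %s (r12 %.4f, r24 %.4f)\n",
              x$arm_a$arm_name, x$arm_a$r12, x$arm_a$r24))
  cat(sprintf("  intervention: %s (r12 %.4f, r24 %.4f)\n",
              x$arm_b$arm_name, x$arm_b$r12, x$arm_b$r24))
  cat("  population:  ", pop, "\n")
  cat("  mode:        ", x$second_cycle_mode, "\n")
  invisible(x)
}

## ---- default base case -----------------------------------------------------

#' The shipped Australian 2019 base case
#'
#' Builds the full default model: two-year IMPERIAL trial outcomes for the
#' Eluvia and Zilver PTX arms, Australian unit costs, the printed six-year
#' national cohort schedule (2019-2024), and per-patient hospital-day
#' intensities calibrated from the first two years of per-arm hospital
#' bed-day expenditure divided by the bed-day cost.
#'
#' Conventions baked into the fixture:
#' * 12-month event rates are exact trial fractions (13/287, 13/145, 1/287,
#'   0/145), not rounded percentages;
#' * 24-month rates are the reported one-decimal percentages (12.7%, 20.1%,
#'   1.5%, 0.7%);
#' * the second cycle recounts the full cumulative 24-month rate
#'   (`cumulative_recount` mode);
#' * the index-procedure payment `c_primary` is set to the percutaneous
#'   intervention tariff (same diagnosis-related group) and is
#'   non-calibrated: it cancels in all between-arm differences;
#' * stent prices are equal in both arms (difference zero), entered as 0 so
#'   price scenarios act multiplicatively on a common baseline offset.
#'
#' @return a `model_config`.
#' @examples
#' cfg <- default_imperial_config()
#' cfg$arm_a$r12 # 13/145
#' @export
default_imperial_config <- function() {
  c_bed_day <- 2003
  ## Year-0/Year-1 hospital-system expenditure per arm (AUD), the most
  ## precise published trace of the day intensities: divide by the per-diem
  ## and invert the two-cycle day formula.
  n01 <- c(5674, 6060)
  hz <- calibrate_day_intensities(n01[1], n01[2],
                                  14184422 / c_bed_day, 46724823 / c_bed_day)
  he <- calibrate_day_intensities(n01[1], n01[2],
                                  6134905 / c_bed_day, 31964449 / c_bed_day)
  zilver <- arm_parameters(
    arm_name = "zilver_ptx",
    r12 = 13 / 145, r24 = 0.201,
    m12_perc = 0.96,  m12_open = 0.04,
    m24_perc = 0.971, m24_open = 0.029,
    a12 = 0 / 145, a24 = 0.007,
    h12 = hz$h12, h24 = hz$h24,
    stent_price = 0
  )
  eluvia <- arm_parameters(
    arm_name = "eluvia",
    r12 = 13 / 287, r24 = 0.127,
    m12_perc = 0.967, m12_open = 0.033,
    m24_perc = 0.957, m24_open = 0.043,
    a12 = 1 / 287, a24 = 0.015,
    h12 = he$h12, h24 = he$h24,
    stent_price = 0
  )
  costs <- cost_schedule(
    c_percutaneous = 5495, c_open = 16411,
    c_amputation = 35354, c_bed_day = c_bed_day,
    c_primary = 5495
  )
  pop <- cohort_schedule(c(5674, 6060, 6474, 6915, 7386, 7890),
                         start_year = 2019)
  model_config(
    arm_a = zilver, arm_b = eluvia, costs = costs, population = pop,
    second_cycle_mode = "cumulative_recount",
    state_shares = default_state_shares()
  )
}

## ---- serialization ---------------------------------------------------------

## %.17g round-trips IEEE doubles exactly; a bare integer-looking value gets
## a ".0" so YAML re-reads it as double, preserving type identity.
yaml_num <- function(y) {
  s <- sprintf("%.17g", y)
  s <- ifelse(grepl("[.eE]", s) | !is.finite(y), s, paste0(s, ".0"))
  structure(s, class = "verbatim")
}

config_to_list <- function(config) {
  arm_list <- function(a) unclass(a)
  pop <- config$population
  pop_list <- if (inherits(pop, "cohort_schedule")) {
    list(type = "cohort_schedule", N = pop$N, year_labels = pop$year_labels)
  } else {
    list(type = "funnel_spec",
         base_population = pop$base_population,
         stages = as.list(pop$stages),
         evp_eligibility = pop$evp_eligibility,
         des_use_rate = pop$des_use_rate,
         growth_rate = pop$growth_rate,
         n_years = pop$n_years,
         start_year = pop$start_year)
  }
  list(
    arm_a = arm_list(config$arm_a),
    arm_b = arm_list(config$arm_b),
    costs = unclass(config$costs),
    population = pop_list,
    n_years = config$n_years,
    second_cycle_mode = config$second_cycle_mode,
    state_shares = if (is.null(config$state_shares)) NULL
                   else as.list(config$state_shares),
    scenario_ranges = config$scenario_ranges,
    enforce_scenario_bounds = config$enforce_scenario_bounds
  )
}

require_keys <- function(x, required, optional, where) {
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown))
    stop_bim(sprintf("unknown key(s) in %s: %s", where,
                     paste(unknown, collapse = ", ")))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_bim(sprintf("missing required field(s) in %s: %s", where,
                     paste(missing, collapse = ", ")))
  invisible(x)
}

arm_from_list <- function(x, where) {
  required <- c("arm_name", "r12", "r24", "m12_perc", "m12_open",
                "m24_perc", "m24_open", "a12", "a24")
  optional <- c("h12", "h24", "stent_price")
  require_keys(x, required, optional, where)
  do.call(arm_parameters, x)
}

config_from_list <- function(x) {
  require_keys(x, c("arm_a", "arm_b", "costs", "population"),
               c("n_years", "second_cycle_mode", "state_shares",
                 "scenario_ranges", "enforce_scenario_bounds"),
               "config")
  require_keys(x$costs,
               c("c_percutaneous", "c_open", "c_amputation", "c_bed_day"),
               "c_primary", "costs")
  pop <- x$population
  if (is.null(pop$type))
    stop_bim("missing required field(s) in population: type")
  population <- switch(
    pop$type,
    cohort_schedule = {
      require_keys(pop, c("type", "N"), "year_labels", "population")
      cohort_schedule(as.numeric(unlist(pop$N)),
                      year_labels = unlist(pop$year_labels))
    },
    funnel_spec = {
      require_keys(pop, c("type", "base_population"),
                   c("stages", "evp_eligibility", "des_use_rate",
                     "growth_rate", "n_years", "start_year"),
                   "population")
      funnel_spec(base_population = pop$base_population,
                  stages = unlist(pop$stages) %||% numeric(),
                  evp_eligibility = pop$evp_eligibility %||% 0.80,
                  des_use_rate = pop$des_use_rate %||% 0.28,
                  growth_rate = pop$growth_rate %||% 0.068,
                  n_years = pop$n_years %||% 6,
                  start_year = pop$start_year %||% 2019)
    },
    stop_bim(sprintf("population type must be 'cohort_schedule' or 'funnel_spec' (got '%s')",
                     pop$type))
  )
  ranges <- x$scenario_ranges %||% default_scenario_ranges()
  ranges <- lapply(ranges, function(r) {
    r <- as.numeric(unlist(r)); r[!is.finite(r) & r > 0] <- Inf; r
  })
  model_config(
    arm_a = arm_from_list(x$arm_a, "arm_a"),
    arm_b = arm_from_list(x$arm_b, "arm_b"),
    costs = do.call(cost_schedule, x$costs),
    population = population,
    n_years = x$n_years,
    second_cycle_mode = x$second_cycle_mode %||% "cumulative_recount",
    state_shares = x$state_shares,
    scenario_ranges = ranges,
    enforce_scenario_bounds = x$enforce_scenario_bounds %||% TRUE
  )
}

#' Write a model configuration to a YAML file
#'
#' Numbers are serialized at full double precision, so
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a `model_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "model_config"))
    stop_bim("`config` must be a model_config")
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop_bim("`path` must be a non-empty file path")
  txt <- yaml::as.yaml(config_to_list(config),
                       handlers = list(numeric = yaml_num))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) stop_bim("cannot write '", path, "': ",
                                              conditionMessage(e)),
                 warning = function(w) stop_bim("cannot write '", path, "': ",
                                                conditionMessage(w)))
  invisible(path)
}

#' Read and validate a model configuration from a YAML file
#'
#' The schema is strict: unknown keys anywhere in the document are rejected,
#' missing required fields are reported by name, and every invariant
#' (rates in \[0,1\], procedure mixes summing to 1, cumulative 24-month rates
#' at least the 12-month rates, non-negative costs) is enforced.
#'
#' @param path path to a YAML configuration.
#' @return a validated `model_config`.
#' @export
load_config <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) ||
      !file.exists(path))
    stop_bim("config file not found: '", paste(path, collapse = ""), "'")
  config_from_list(yaml::read_yaml(path))
}

#' Path to the shipped base-case configuration
#'
#' @return file path of the `imperial_au_2019.yaml` fixture installed with
#'   the package.
#' @export
imperial_config_path <- function() {
  system.file("extdata", "imperial_au_2019.yaml", package = "stentbim",
              mustWork = TRUE)
}
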