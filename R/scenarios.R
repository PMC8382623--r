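#' Specify a one-way scenario
#'
#' A sparse set of overrides applied to a base configuration. Population
#' overrides (EVP eligibility, device use rate, explicit cohort factor) act
#' multiplicatively on the cohort schedule — the engine is linear in the
#' schedule, so this is exact. Price overrides multiply the per-arm stent
#' price; the bed-day override multiplies the per-diem.
#'
#' @param name unique scenario label.
#' @param evp_eligibility override of the EVP eligibility rate.
#' @param des_use_rate override of the device use rate.
#' @param stent_price_multiplier_a,stent_price_multiplier_b per-arm stent
#'   price multipliers (use both for an equal change).
#' @param bed_day_multiplier multiplier on the cost per bed-day.
#' @param cohort_factor explicit multiplicative factor on the schedule.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          evp_eligibility = NULL,
                          des_use_rate = NULL,
                          stent_price_multiplier_a = NULL,
                          stent_price_multiplier_b = NULL,
                          bed_day_multiplier = NULL,
                          cohort_factor = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_bim("`name` must be a non-empty string")
  mults <- c(stent_price_multiplier_a, stent_price_multiplier_b,
             bed_day_multiplier, cohort_factor)
  if (any(mults <= 0)) stop_bim("scenario multipliers must be positive")
  structure(list(name = name,
                 evp_eligibility = evp_eligibility,
                 des_use_rate = des_use_rate,
                 stent_price_multiplier_a = stent_price_multiplier_a,
                 stent_price_multiplier_b = stent_price_multiplier_b,
                 bed_day_multiplier = bed_day_multiplier,
                 cohort_factor = cohort_factor),
            class = "scenario_spec")
}

check_bound <- function(value, bound, what, enforce) {
  if (is.null(value) || is.null(bound)) return(invisible())
  if (value < bound[1] || value > bound[2]) {
    msg <- sprintf("scenario override `%s` = %g is outside the bound [%g, %g]",
                   what, value, bound[1], bound[2])
    if (enforce) stop_bim(msg) else warning(msg, call. = FALSE)
  }
  invisible()
}

## Base population rates the scenario factors are taken relative to.
base_population_rates <- function(config) {
  pop <- config$population
  if (inherits(pop, "funnel_spec"))
    list(evp = pop$evp_eligibility, des = pop$des_use_rate)
  else
    list(evp = 0.80, des = 0.28)
}

#' Apply a scenario and rerun the model
#'
#' Applies the overrides in `spec` to `config` (population overrides become
#' a multiplicative factor `new_rate / base_rate` on the cohort schedule),
#' validates each override against the configured bounds, and reruns the
#' full pipeline. A scenario with no overrides reproduces the base case
#' exactly.
#'
#' @param config a [model_config()].
#' @param spec a [scenario_spec()].
#' @return the scenario's [budget_impact()] result, with the full fitted
#'   [run_bim()] object attached as attribute `"model"`.
#' @examples
#' res <- run_scenario(default_imperial_config(),
#'                     scenario_spec("low_use", des_use_rate = 0.10))
#' round_half_up(res$totals$tlr_avoided) # 1499
#' @export
run_scenario <- function(config, spec) {
  if (!inherits(config, "model_config"))
    stop_bim("`config` must be a model_config")
  if (!inherits(spec, "scenario_spec"))
    stop_bim("`spec` must be a scenario_spec")
  enforce <- config$enforce_scenario_bounds
  rg <- config$scenario_ranges
  check_bound(spec$evp_eligibility, rg$evp_eligibility, "evp_eligibility",
              enforce)
  check_bound(spec$des_use_rate, rg$des_use_rate, "des_use_rate", enforce)
  check_bound(spec$stent_price_multiplier_a, rg$stent_price_multiplier,
              "stent_price_multiplier_a", enforce)
  check_bound(spec$stent_price_multiplier_b, rg$stent_price_multiplier,
              "stent_price_multiplier_b", enforce)
  check_bound(spec$bed_day_multiplier, rg$bed_day_multiplier,
              "bed_day_multiplier", enforce)
  check_bound(spec$cohort_factor, rg$cohort_factor, "cohort_factor", enforce)

  base <- base_population_rates(config)
  phi <- spec$cohort_factor %||% 1
  if (!is.null(spec$evp_eligibility))
    phi <- phi * spec$evp_eligibility / base$evp
  if (!is.null(spec$des_use_rate))
    phi <- phi * spec$des_use_rate / base$des

  cfg <- config
  cfg$population <- scale_schedule(resolve_population(config), phi)
  if (!is.null(spec$stent_price_multiplier_a))
    cfg$arm_a$stent_price <- cfg$arm_a$stent_price *
      spec$stent_price_multiplier_a
  if (!is.null(spec$stent_price_multiplier_b))
    cfg$arm_b$stent_price <- cfg$arm_b$stent_price *
      spec$stent_price_multiplier_b
  if (!is.null(spec$bed_day_multiplier))
    cfg$costs$c_bed_day <- cfg$costs$c_bed_day * spec$bed_day_multiplier

  fit <- run_bim(cfg)
  res <- fit$impact
  attr(res, "scenario") <- spec$name
  attr(res, "model") <- fit
  res
}

#' Run an ordered set of scenarios
#'
#' One row per scenario with total TLRs avoided, days averted and savings
#' under both perspectives, plus deltas against the base case (the
#' unmodified `config`), suitable for a tornado-style report.
#'
#' @param config a [model_config()].
#' @param specs list of [scenario_spec()] objects with unique names.
#' @return a data frame, one row per scenario, unrounded values.
#' @export
sweep_scenarios <- function(config, specs) {
  if (!is.list(specs))
    stop_bim("`specs` must be a list of scenario_spec objects")
  nms <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nms))
    stop_bim("duplicate scenario names: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
  cols <- c("tlr_avoided", "days_averted", "healthcare_savings",
            "hospital_savings")
  if (!length(specs)) {
    out <- as.data.frame(c(list(scenario = character()),
                           stats::setNames(rep(list(numeric()), 8),
                                           c(cols, paste0("delta_", cols)))))
    return(out)
  }
  base <- run_bim(config)$impact$totals
  rows <- lapply(specs, function(s) {
    t <- run_scenario(config, s)$totals
    row <- c(list(scenario = s$name), t[cols],
             stats::setNames(Map(`-`, t[cols], base[cols]),
                             paste0("delta_", cols)))
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

## ---- state disaggregation --------------------------------------------------

#' Subnational partition of the treated cohort
#'
#' @param shares named fractions of the national treated cohort per
#'   state/territory. Each in \[0,1\]; the sum may be below 1 (part of the
#'   national cohort can remain unallocated).
#' @return an object of class `state_partition`.
#' @export
state_partition <- function(shares) {
  shares <- unlist(shares)
  if (is.null(names(shares)) || any(names(shares) == ""))
    stop_bim("`shares` must be named")
  for (s in names(shares)) check_fraction(shares[[s]], paste0("shares.", s))
  if (sum(shares) > 1 + 1e-9)
    stop_bim("state shares must sum to at most 1")
  structure(list(shares = shares), class = "state_partition")
}

#' Default Australian state/territory shares
#'
#' Back-calculated from published state-level treated-cohort counts at the
#' base-case device use rate divided by the national six-year total (40,399
#' patients). The printed state cohorts leave about 1.6% of the national
#' cohort unallocated, so the shares deliberately do not sum to 1.
#'
#' @return named numeric vector of shares.
#' @export
default_state_shares <- function() {
  c("NSW & ACT" = 13377, "VIC" = 10220, "SA" = 2787, "WA" = 4164,
    "NT" = 399, "QLD" = 7969, "TAS" = 845) / 40399
}

#' Scale a national result down to states/territories
#'
#' Every unrounded national quantity is multiplied by each state's share;
#' display rounding happens only in the report writers. Summing the state
#' results recovers the national result times the total allocated share.
#'
#' @param national_result a [budget_impact()] result (or a `bim` object,
#'   whose impact is used).
#' @param partition a [state_partition()]; defaults to
#'   [default_state_shares()].
#' @param states optional subset of state labels; unknown labels error.
#' @return named list of `budget_impact_result` objects, one per state.
#' @export
disaggregate <- function(national_result,
                         partition = state_partition(default_state_shares()),
                         states = NULL) {
  if (inherits(national_result, "bim"))
    national_result <- national_result$impact
  if (!inherits(national_result, "budget_impact_result"))
    stop_bim("`national_result` must be a budget_impact_result or bim")
  if (!inherits(partition, "state_partition"))
    stop_bim("`partition` must be a state_partition")
  shares <- partition$shares
  if (!is.null(states)) {
    unknown <- setdiff(states, names(shares))
    if (length(unknown))
      stop_bim("unknown state label(s): ", paste(unknown, collapse = ", "))
    shares <- shares[states]
  }
  num <- c("tlr_avoided", "amputations_avoided", "days_averted",
           "healthcare_savings", "hospital_savings")
  out <- lapply(names(shares), function(st) {
    r <- national_result
    r$rows[num] <- r$rows[num] * shares[[st]]
    r$totals[num] <- lapply(r$totals[num], `*`, shares[[st]])
    attr(r, "state") <- st
    attr(r, "share") <- shares[[st]]
    r
  })
  stats::setNames(out, names(shares))
}
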