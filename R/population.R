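#' Epidemiological funnel specification
#'
#' A funnel converts a national base population into the count of patients
#' newly treated with the device in the first model year, by successive
#' multiplication: arbitrary named prevalence/eligibility stages, then the
#' endovascular-procedure (EVP) eligibility rate, then the device use rate.
#' Subsequent years grow geometrically at `growth_rate`.
#'
#' @param base_population persons entering the top of the funnel.
#' @param stages named numeric vector of fractions applied multiplicatively
#'   (may be empty if `base_population` already reflects them).
#' @param evp_eligibility fraction eligible for an endovascular procedure
#'   (base case 0.80).
#' @param des_use_rate fraction of eligible procedures using the device
#'   (base case 0.28).
#' @param growth_rate annual multiplicative growth of procedure volume
#'   (base case approximately 0.068).
#' @param n_years number of annual cohorts.
#' @param start_year first calendar year label.
#' @return an object of class `funnel_spec`.
#' @export
funnel_spec <- function(base_population, stages = numeric(),
                        evp_eligibility = 0.80, des_use_rate = 0.28,
                        growth_rate = 0.068, n_years = 6,
                        start_year = 2019) {
  check_nonneg(base_population, "base_population")
  stages <- unlist(stages) %||% numeric()
  if (length(stages)) {
    for (i in seq_along(stages))
      check_fraction(stages[[i]],
                     paste0("stages.", names(stages)[i] %||% i))
  }
  check_fraction(evp_eligibility, "evp_eligibility")
  check_fraction(des_use_rate, "des_use_rate")
  if (!is.numeric(growth_rate) || growth_rate <= -1)
    stop_bim("`growth_rate` must be > -1")
  if (n_years < 1) stop_bim("`n_years` must be at least 1")
  structure(list(base_population = base_population,
                 stages = stages,
                 evp_eligibility = evp_eligibility,
                 des_use_rate = des_use_rate,
                 growth_rate = growth_rate,
                 n_years = as.integer(n_years),
                 start_year = as.integer(start_year)),
            class = "funnel_spec")
}

#' Apply a funnel to obtain the first-year treated count
#'
#' @param spec a [funnel_spec()].
#' @return unrounded number of patients treated in year 0.
#' @examples
#' apply_funnel(funnel_spec(5674 / (0.80 * 0.28))) # 5674
#' @export
apply_funnel <- function(spec) {
  if (!inherits(spec, "funnel_spec")) stop_bim("`spec` must be a funnel_spec")
  spec$base_population * prod(spec$stages) *
    spec$evp_eligibility * spec$des_use_rate
}

#' Annual treated-cohort schedule
#'
#' The number of patients newly treated in each model year. Values are kept
#' unrounded internally; rounding happens only at report time.
#'
#' @param N numeric vector of newly treated patients per year.
#' @param year_labels optional calendar-year labels (defaults to
#'   `start_year`, `start_year + 1`, ...).
#' @param start_year first calendar year when `year_labels` is absent.
#' @return an object of class `cohort_schedule`.
#' @export
cohort_schedule <- function(N, year_labels = NULL, start_year = 2019) {
  check_nonneg(N, "N")
  if (length(N) < 1) stop_bim("`N` must have at least one year")
  if (is.null(year_labels))
    year_labels <- seq(start_year, length.out = length(N))
  if (length(year_labels) != length(N))
    stop_bim("`year_labels` must match the length of `N`")
  structure(list(N = as.numeric(N), year_labels = as.integer(year_labels)),
            class = "cohort_schedule")
}

#' @export
print.cohort_schedule <- function(x, ...) {
  cat("Cohort schedule (", length(x$N), " years, total ",
      fmt_int(sum(x$N)), " patients)\n", sep = "")
  print(stats::setNames(round_half_up(x$N), x$year_labels))
  invisible(x)
}

#' Grow a first-year count into a full schedule
#'
#' `N_t = year0 * (1 + g)^t`, unrounded.
#'
#' @param year0 treated patients in the first model year.
#' @param growth_rate annual multiplicative growth `g` (> -1).
#' @param n_years number of years.
#' @param start_year first calendar-year label.
#' @return a [cohort_schedule()].
#' @examples
#' build_cohort_schedule(5674, 0.068, 6)$N[2] # 6059.832, displays 6060
#' @export
build_cohort_schedule <- function(year0, growth_rate, n_years,
                                  start_year = 2019) {
  check_nonneg(year0, "year0")
  if (!is.numeric(growth_rate) || growth_rate <= -1)
    stop_bim("`growth_rate` must be > -1")
  if (n_years < 1) stop_bim("`n_years` must be at least 1")
  cohort_schedule(year0 * (1 + growth_rate)^(seq_len(n_years) - 1),
                  start_year = start_year)
}

#' Scale a cohort schedule
#'
#' Multiplies every yearly cohort by `factor`. Because the whole engine is
#' linear (homogeneous of degree 1) in the schedule, this expresses
#' population scenarios exactly: a device-use rate of 10% against a 28% base
#' is `scale_schedule(s, 10/28)`.
#'
#' @param schedule a [cohort_schedule()].
#' @param factor non-negative multiplier.
#' @return a scaled [cohort_schedule()].
#' @export
scale_schedule <- function(schedule, factor) {
  if (!inherits(schedule, "cohort_schedule"))
    stop_bim("`schedule` must be a cohort_schedule")
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 0)
    stop_bim("`factor` must be a single non-negative number")
  cohort_schedule(schedule$N * factor, year_labels = schedule$year_labels)
}

## Resolve a config's population field to an explicit schedule.
resolve_population <- function(config) {
  pop <- config$population
  if (inherits(pop, "cohort_schedule")) return(pop)
  build_cohort_schedule(apply_funnel(pop), pop$growth_rate, pop$n_years,
                        start_year = pop$start_year)
}
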