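#' Specification for a synthetic two-arm trial
#'
#' Ground truth plus sampling sizes for generating trial-like observed
#' inputs: binomial event counts per arm (12-month, with cumulative
#' 24-month counts at least the 12-month counts by construction), observed
#' procedure mixes, and noisy per-year hospital-day totals.
#'
#' @param seed integer master seed; every generator derives its own named
#'   stream from it.
#' @param n_per_arm patients per arm.
#' @param true_arm_a,true_arm_b ground-truth [arm_parameters()].
#' @param day_noise_sd standard deviation (days) of Gaussian noise added to
#'   yearly day totals, truncated at zero.
#' @return an object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(seed, n_per_arm,
                                 true_arm_a, true_arm_b,
                                 day_noise_sd = 0) {
  if (!is.numeric(seed) || length(seed) != 1L) stop_bim("`seed` must be a number")
  if (!is.numeric(n_per_arm) || n_per_arm < 1)
    stop_bim("`n_per_arm` must be at least 1")
  check_nonneg(day_noise_sd, "day_noise_sd")
  validate_arm_parameters(true_arm_a)
  validate_arm_parameters(true_arm_b)
  structure(list(seed = as.integer(seed), n_per_arm = as.integer(n_per_arm),
                 true_arm_a = true_arm_a, true_arm_b = true_arm_b,
                 day_noise_sd = day_noise_sd),
            class = "synthetic_trial_spec")
}

## Draw one arm's observed parameters from its truth.
sample_arm <- function(truth, n) {
  k12 <- stats::rbinom(1, n, truth$r12)
  ## cumulative: extra 12-to-24-month events among the not-yet-event patients
  p_inc <- if (truth$r12 < 1) (truth$r24 - truth$r12) / (1 - truth$r12) else 0
  k24 <- k12 + stats::rbinom(1, n - k12, min(max(p_inc, 0), 1))
  ka12 <- stats::rbinom(1, n, truth$a12)
  pa_inc <- if (truth$a12 < 1) (truth$a24 - truth$a12) / (1 - truth$a12) else 0
  ka24 <- ka12 + stats::rbinom(1, n - ka12, min(max(pa_inc, 0), 1))
  mix <- function(k, p) if (k > 0) stats::rbinom(1, k, p) / k else p
  m12 <- mix(k12, truth$m12_perc)
  m24 <- mix(k24, truth$m24_perc)
  arm_parameters(
    arm_name = paste0(truth$arm_name, "_observed"),
    r12 = k12 / n, r24 = k24 / n,
    m12_perc = m12, m12_open = 1 - m12,
    m24_perc = m24, m24_open = 1 - m24,
    a12 = ka12 / n, a24 = ka24 / n,
    h12 = truth$h12, h24 = truth$h24,
    stent_price = truth$stent_price
  )
}

#' Simulate observed trial outcome parameters
#'
#' Event counts are binomial draws at the true rates; 24-month counts are
#' the 12-month counts plus a conditional binomial among event-free
#' patients, so observed cumulative rates are monotone by construction and
#' always pass validation. Procedure mixes are binomial fractions of the
#' observed events (the true mix when no events occur). Day intensities and
#' stent prices pass through unchanged. Pure function of `(seed, spec)`.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return list with observed [arm_parameters()] `arm_a` and `arm_b`.
#' @export
simulate_trial <- function(spec) {
  if (!inherits(spec, "synthetic_trial_spec"))
    stop_bim("`spec` must be a synthetic_trial_spec")
  list(
    arm_a = with_stream(spec$seed, "trial_arm_a",
                        function() sample_arm(spec$true_arm_a, spec$n_per_arm)),
    arm_b = with_stream(spec$seed, "trial_arm_b",
                        function() sample_arm(spec$true_arm_b, spec$n_per_arm))
  )
}

#' Simulate noisy observed hospital-day totals
#'
#' For each arm, the yearly day totals of the exact projection under
#' `config` plus Gaussian noise with `spec$day_noise_sd`, truncated at
#' zero. With zero noise the projection is returned exactly, so
#' [calibrate_day_intensities()] applied to the first two years recovers
#' the true intensities algebraically.
#'
#' @param config a [model_config()].
#' @param spec a [synthetic_trial_spec()] (supplies seed and noise sd).
#' @return list of numeric per-year day-total vectors, `arm_a` and `arm_b`.
#' @export
simulate_observed_days <- function(config, spec) {
  if (!inherits(config, "model_config"))
    stop_bim("`config` must be a model_config")
  if (!inherits(spec, "synthetic_trial_spec"))
    stop_bim("`spec` must be a synthetic_trial_spec")
  cohorts <- resolve_population(config)
  noisy <- function(arm, stream) {
    d <- project_events(cohorts, arm,
                        mode = config$second_cycle_mode)$rows$hospital_days_total
    if (spec$day_noise_sd == 0) return(d)
    with_stream(spec$seed, stream, function()
      pmax(0, d + stats::rnorm(length(d), 0, spec$day_noise_sd)))
  }
  list(arm_a = noisy(config$arm_a, "days_arm_a"),
       arm_b = noisy(config$arm_b, "days_arm_b"))
}

#' Generate a random valid model configuration
#'
#' Draws rates, mixes, costs, a cohort schedule and a 3- to 8-year horizon
#' from wide but valid ranges, for property-based testing of the full
#' pipeline. Every generated configuration passes validation and
#' serialization round-trips. Pure function of `seed`.
#'
#' @param seed integer seed.
#' @return a `model_config`.
#' @export
random_config <- function(seed) {
  with_stream(seed, "random_config", function() {
    rand_arm <- function(nm) {
      r12 <- stats::runif(1, 0, 0.3)
      r24 <- r12 + stats::runif(1, 0, 0.3)
      a12 <- stats::runif(1, 0, 0.05)
      a24 <- a12 + stats::runif(1, 0, 0.05)
      m12 <- stats::runif(1, 0.5, 1)
      m24 <- stats::runif(1, 0.5, 1)
      arm_parameters(nm, r12 = r12, r24 = r24,
                     m12_perc = m12, m12_open = 1 - m12,
                     m24_perc = m24, m24_open = 1 - m24,
                     a12 = a12, a24 = a24,
                     h12 = stats::runif(1, 0, 3),
                     h24 = stats::runif(1, 0, 5),
                     stent_price = stats::runif(1, 0, 5000))
    }
    n_years <- sample(3:8, 1)
    model_config(
      arm_a = rand_arm("comparator"),
      arm_b = rand_arm("intervention"),
      costs = cost_schedule(
        c_percutaneous = stats::runif(1, 1000, 10000),
        c_open = stats::runif(1, 10000, 30000),
        c_amputation = stats::runif(1, 20000, 50000),
        c_bed_day = stats::runif(1, 500, 4000),
        c_primary = stats::runif(1, 0, 10000)),
      population = cohort_schedule(stats::runif(n_years, 100, 10000)),
      second_cycle_mode = "cumulative_recount"
    )
  })
}
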