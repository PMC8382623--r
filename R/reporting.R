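#' Render the per-year national results table
#'
#' Lays the model out in the conventional budget-impact shape: the treated
#' population row, then per-arm blocks (CD-TLRs, hospital days for adverse
#' events, healthcare-system cost, hospital-system cost), then the
#' difference block. One column per model year plus a `Total` column.
#'
#' Every displayed number is the half-up rounding of the corresponding
#' unrounded engine value, and the `Total` column is rounded from the
#' unrounded sum — so a total can differ by one unit from the sum of its
#' rounded cells. Rendering is a pure function of the fitted object; no
#' model arithmetic happens here.
#'
#' @param fit a [run_bim()] result.
#' @return a data frame with columns `section`, `metric`, one column per
#'   year label, and `Total`.
#' @export
render_table4 <- function(fit) {
  if (!inherits(fit, "bim"))
    stop_bim("`fit` must be a bim object from run_bim()")
  needed <- c("cohorts", "projection_a", "projection_b", "cost_a", "cost_b",
              "impact")
  if (any(vapply(needed, function(f) is.null(fit[[f]]), logical(1))))
    stop_bim("incomplete model result: missing ",
             paste(needed[vapply(needed, function(f) is.null(fit[[f]]),
                                 logical(1))], collapse = ", "))
  yl <- paste0("Y", fit$cohorts$year_labels)
  row <- function(section, metric, values) {
    out <- data.frame(section = section, metric = metric)
    vals <- round_half_up(c(values, sum(values)))
    out[c(yl, "Total")] <- as.list(vals)
    out
  }
  arm_block <- function(nm, proj, cost) rbind(
    row(nm, "CD-TLRs", proj$rows$tlr_total),
    row(nm, "Hospital days for AEs", proj$rows$hospital_days_total),
    row(nm, "Healthcare system cost (AUD)", cost$rows$healthcare_total),
    row(nm, "Hospital system cost (AUD)", cost$rows$hospital_total)
  )
  imp <- fit$impact$rows
  rbind(
    row("population", "Treated patients", fit$cohorts$N),
    arm_block(fit$config$arm_a$arm_name, fit$projection_a, fit$cost_a),
    arm_block(fit$config$arm_b$arm_name, fit$projection_b, fit$cost_b),
    row("difference", "CD-TLRs avoided", imp$tlr_avoided),
    row("difference", "Hospital days averted", imp$days_averted),
    row("difference", "Healthcare system savings (AUD)",
        imp$healthcare_savings),
    row("difference", "Hospital system savings (AUD)", imp$hospital_savings)
  )
}

## "low–high" range string (en dash); thousands separators only for display.
fmt_range <- function(lo, hi, display, digits = 0) {
  f <- function(x) {
    if (digits == 0) {
      if (display) fmt_int(x) else sprintf("%d", as.integer(round_half_up(x)))
    } else sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  }
  paste0(f(lo), "–", f(hi))
}

#' Render the state/territory results table
#'
#' For each state, scales the national unrounded results by the state's
#' share at the low and high device-use rates and renders each metric as a
#' "low–high" range. Patient counts, TLRs avoided and days averted are
#' whole numbers; savings are reported in millions of AUD to three
#' decimals.
#'
#' @param fit a [run_bim()] result at the base device-use rate.
#' @param partition a [state_partition()]; default the shipped shares.
#' @param use_rates length-2 device-use rates spanning the range (default
#'   10% to the 28% base).
#' @param base_use_rate the device-use rate `fit` was run at.
#' @param display if `TRUE` (default) integers carry thousands separators;
#'   set `FALSE` for machine-readable CSV.
#' @return a data frame, one row per state, range strings per metric.
#' @export
render_state_table <- function(fit,
                               partition = state_partition(
                                 fit$config$state_shares %||%
                                   default_state_shares()),
                               use_rates = c(0.10, 0.28),
                               base_use_rate = 0.28,
                               display = TRUE) {
  if (!inherits(fit, "bim")) stop_bim("`fit` must be a bim object")
  if (length(use_rates) != 2L || use_rates[1] > use_rates[2])
    stop_bim("`use_rates` must be an increasing pair of rates")
  phis <- use_rates / base_use_rate
  tot_pat <- sum(fit$cohorts$N)
  t <- fit$impact$totals
  shares <- partition$shares
  out <- lapply(names(shares), function(st) {
    s <- shares[[st]]
    rng <- function(x, digits = 0)
      fmt_range(x * s * phis[1], x * s * phis[2], display, digits)
    data.frame(
      state = st,
      patients_treated = rng(tot_pat),
      tlr_avoided = rng(t$tlr_avoided),
      days_averted = rng(t$days_averted),
      healthcare_savings_m = rng(t$healthcare_savings / 1e6, digits = 3),
      hospital_savings_m = rng(t$hospital_savings / 1e6, digits = 3)
    )
  })
  do.call(rbind, out)
}

#' Render a scenario sweep for reporting
#'
#' Rounds the unrounded [sweep_scenarios()] output half-up to whole units
#' for counts/days and whole AUD for savings.
#'
#' @param sweep a [sweep_scenarios()] data frame.
#' @return data frame with the same columns, display-rounded.
#' @export
render_scenario_table <- function(sweep) {
  num <- vapply(sweep, is.numeric, logical(1))
  sweep[num] <- lapply(sweep[num], round_half_up)
  sweep
}

#' Stable hash of a model configuration
#'
#' MD5 of the canonical full-precision YAML serialization; identical
#' configurations hash identically across sessions.
#'
#' @param config a `model_config`.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a report table to CSV or JSON
#'
#' CSV is RFC-4180 (quoted where needed, no thousands separators in numeric
#' columns); JSON carries the identical numbers. Output depends only on the
#' table contents, so identical inputs produce byte-identical files.
#'
#' @param table a data frame.
#' @param path output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(table, path,
                               format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
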