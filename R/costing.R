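#' Blended unit cost of a TLR under a procedure mix
#'
#' @param mix_perc,mix_open fractions of percutaneous and open procedures;
#'   must sum to 1.
#' @param costs a [cost_schedule()].
#' @return blended AUD cost per TLR event.
#' @examples
#' cs <- cost_schedule(5495, 16411, 35354, 2003)
#' tlr_unit_cost(0.96, 0.04, cs) # 5931.64
#' @export
tlr_unit_cost <- function(mix_perc, mix_open, costs) {
  if (abs(mix_perc + mix_open - 1) > 1e-9)
    stop_bim("procedure mix must sum to 1")
  mix_perc * costs$c_percutaneous + mix_open * costs$c_open
}

#' Cost one arm's projection under both perspectives
#'
#' Per model year:
#' * `primary_cost = N_t * (c_primary + stent_price)` — index procedures;
#' * `tlr_cost` — TLR events split percutaneous/open by cycle-specific mixes
#'   and priced at the respective tariffs;
#' * `amputation_cost = amputations * c_amputation`;
#' * `healthcare_total = primary + tlr + amputation` — the activity-based
#'   funding (payer) perspective;
#' * `hospital_total = hospital_days * c_bed_day` — the bed-day (hospital)
#'   perspective, which by construction ignores all procedure tariffs.
#'
#' All values unrounded AUD.
#'
#' @param projection an [project_events()] result.
#' @param arm the matching [arm_parameters()] (procedure mixes, stent price).
#' @param costs a [cost_schedule()].
#' @return an object of class `arm_cost_table` with per-year `rows`,
#'   unrounded `totals`, and the projection attached.
#' @export
cost_arm <- function(projection, arm, costs) {
  if (!inherits(projection, "arm_projection"))
    stop_bim("`projection` must be an arm_projection")
  if (!inherits(arm, "arm_parameters"))
    stop_bim("`arm` must be an arm_parameters object")
  if (!inherits(costs, "cost_schedule"))
    stop_bim("`costs` must be a cost_schedule")
  pr <- projection$rows
  split <- split_tlr_by_procedure(pr$tlr_first_cycle, pr$tlr_second_cycle,
                                  arm)
  rows <- data.frame(
    year_index = pr$year_index,
    year_label = pr$year_label,
    cohort = pr$cohort,
    primary_cost = pr$cohort * (costs$c_primary + arm$stent_price),
    tlr_cost = split$perc * costs$c_percutaneous +
               split$open * costs$c_open,
    amputation_cost = pr$amputations_total * costs$c_amputation,
    hospital_total = pr$hospital_days_total * costs$c_bed_day
  )
  rows$healthcare_total <-
    rows$primary_cost + rows$tlr_cost + rows$amputation_cost
  totals <- as.list(colSums(rows[c("primary_cost", "tlr_cost",
                                   "amputation_cost", "healthcare_total",
                                   "hospital_total")]))
  structure(list(arm_name = projection$arm_name, rows = rows,
                 totals = totals, projection = projection),
            class = "arm_cost_table")
}

#' Between-arm budget impact
#'
#' Element-wise differences comparator minus intervention, per year and in
#' total, all unrounded: TLRs avoided, hospital days averted, savings to the
#' healthcare system (activity-based funding) and to hospitals (bed-days).
#' The index-procedure payment and any equal stent price cancel exactly in
#' `healthcare_savings`; `hospital_savings` depends only on bed-days and the
#' per-diem.
#'
#' @param table_a comparator [cost_arm()] table.
#' @param table_b intervention [cost_arm()] table.
#' @return an object of class `budget_impact_result` with per-year `rows`
#'   (`tlr_avoided`, `amputations_avoided`, `days_averted`,
#'   `healthcare_savings`, `hospital_savings`) and unrounded `totals`.
#' @export
budget_impact <- function(table_a, table_b) {
  if (!inherits(table_a, "arm_cost_table") ||
      !inherits(table_b, "arm_cost_table"))
    stop_bim("inputs must be arm_cost_table objects")
  if (nrow(table_a$rows) != nrow(table_b$rows))
    stop_bim("arm tables cover different year spans")
  pa <- table_a$projection$rows
  pb <- table_b$projection$rows
  rows <- data.frame(
    year_index = pa$year_index,
    year_label = pa$year_label,
    tlr_avoided = pa$tlr_total - pb$tlr_total,
    amputations_avoided = pa$amputations_total - pb$amputations_total,
    days_averted = pa$hospital_days_total - pb$hospital_days_total,
    healthcare_savings = table_a$rows$healthcare_total -
                         table_b$rows$healthcare_total,
    hospital_savings = table_a$rows$hospital_total -
                       table_b$rows$hospital_total
  )
  totals <- as.list(colSums(rows[c("tlr_avoided", "amputations_avoided",
                                   "days_averted", "healthcare_savings",
                                   "hospital_savings")]))
  structure(list(arm_a = table_a$arm_name, arm_b = table_b$arm_name,
                 rows = rows, totals = totals),
            class = "budget_impact_result")
}

#' @export
print.budget_impact_result <- function(x, ...) {
  cat("Budget impact: ", x$arm_a, " minus ", x$arm_b, "\n", sep = "")
  df <- x$rows[c("year_label", "tlr_avoided", "days_averted",
                 "healthcare_savings", "hospital_savings")]
  df[-1] <- lapply(df[-1], round_half_up)
  print(df, row.names = FALSE)
  cat(sprintf(
    "Totals: %s TLRs avoided, %s days averted, $%s healthcare, $%s hospital\n",
    fmt_int(x$totals$tlr_avoided), fmt_int(x$totals$days_averted),
    fmt_int(x$totals$healthcare_savings), fmt_int(x$totals$hospital_savings)))
  invisible(x)
}
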