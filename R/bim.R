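#' Run the full budget impact model
#'
#' Resolves the population to an annual cohort schedule, projects events for
#' both arms under the configured second-cycle convention, costs each arm
#' under both perspectives, and differences the arms.
#'
#' @param config a [model_config()]; defaults to the shipped base case.
#' @param mode optional override of `config$second_cycle_mode`.
#' @return an object of class `bim` holding the `config`, the resolved
#'   `cohorts`, per-arm projections (`projection_a`, `projection_b`) and
#'   cost tables (`cost_a`, `cost_b`), and the between-arm `impact`
#'   ([budget_impact()] result). All stored values are unrounded.
#' @examples
#' fit <- run_bim()
#' summary(fit)
#' @export
run_bim <- function(config = default_imperial_config(), mode = NULL) {
  if (!inherits(config, "model_config"))
    stop_bim("`config` must be a model_config")
  mode <- mode %||% config$second_cycle_mode
  cohorts <- resolve_population(config)
  pa <- project_events(cohorts, config$arm_a, mode = mode)
  pb <- project_events(cohorts, config$arm_b, mode = mode)
  ca <- cost_arm(pa, config$arm_a, config$costs)
  cb <- cost_arm(pb, config$arm_b, config$costs)
  structure(list(config = config, mode = mode, cohorts = cohorts,
                 projection_a = pa, projection_b = pb,
                 cost_a = ca, cost_b = cb,
                 impact = budget_impact(ca, cb)),
            class = "bim")
}

#' @export
print.bim <- function(x, ...) {
  t <- x$impact$totals
  cat("Budget impact model (", length(x$cohorts$N), " years, mode ",
      x$mode, ")\n", sep = "")
  cat(sprintf("  treated patients: %s\n", fmt_int(sum(x$cohorts$N))))
  cat(sprintf("  %s vs %s:\n", x$config$arm_a$arm_name,
              x$config$arm_b$arm_name))
  cat(sprintf("    TLRs avoided:       %s\n", fmt_int(t$tlr_avoided)))
  cat(sprintf("    bed-days averted:   %s\n", fmt_int(t$days_averted)))
  cat(sprintf("    healthcare savings: $%s\n", fmt_int(t$healthcare_savings)))
  cat(sprintf("    hospital savings:   $%s\n", fmt_int(t$hospital_savings)))
  invisible(x)
}

#' @export
summary.bim <- function(object, ...) {
  tab <- render_table4(object)
  structure(list(table = tab, mode = object$mode), class = "summary.bim")
}

#' @export
print.summary.bim <- function(x, ...) {
  cat("Base-shape results table (mode ", x$mode, ")\n", sep = "")
  tab <- x$table
  disp <- tab
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], fmt_int)
  print(disp, row.names = FALSE, right = TRUE)
  invisible(x)
}

#' @export
plot.bim <- function(x, which = c("hospital_savings", "healthcare_savings",
                                  "days_averted", "tlr_avoided"), ...) {
  which <- match.arg(which)
  v <- x$impact$rows[[which]]
  graphics::barplot(v, names.arg = x$impact$rows$year_label,
                    main = paste("Per-year", gsub("_", " ", which)),
                    ylab = gsub("_", " ", which), col = "steelblue", ...)
  invisible(x)
}
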