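# Scenario runner and incremental cost-effectiveness comparison.

#' Construct a scenario result
#'
#' Usually produced by [run_scenario()]; the constructor is exported so that
#' published per-arm values can be fed directly into
#' [compare_scenarios()] (e.g. to verify incremental arithmetic against a
#' printed table).
#'
#' @param arm `"status_quo"` or `"program"`.
#' @param mean_cost,mean_life_expectancy,mean_qaly per-person means (USD,
#'   undiscounted years, discounted QALYs).
#' @param n_persons cohort size behind the means.
#' @param root_seed root seed of the run (`NA` for hand-entered values).
#' @param se named numeric vector of Monte-Carlo standard errors
#'   (`cost`, `life_expectancy`, `qaly`); `NA` when unavailable.
#' @param components optional per-person component list kept for
#'   calibration/frontier reuse.
#' @param persons optional per-person accrual data frame.
#' @return An object of class `scenario_result`.
#' @export
scenario_result <- function(arm, mean_cost, mean_life_expectancy, mean_qaly,
                            n_persons, root_seed = NA_integer_,
                            se = c(cost = NA_real_, life_expectancy = NA_real_, qaly = NA_real_),
                            components = NULL, persons = NULL) {
  if (n_persons < 1L) stop_field("n_persons", "must be >= 1")
  if (any(!is.na(se) & se < 0)) stop_field("se", "standard errors must be >= 0")
  structure(
    list(
      arm = arm,
      mean_cost = mean_cost,
      mean_life_expectancy = mean_life_expectancy,
      mean_qaly = mean_qaly,
      se = se,
      n_persons = as.integer(n_persons),
      root_seed = root_seed,
      components = components,
      persons = persons
    ),
    class = "scenario_result"
  )
}

#' Run one screening scenario over a cohort
#'
#' Simulates every person's life course under the policy and aggregates to
#' per-person means with Monte-Carlo standard errors (sample SD / sqrt(n)).
#' Per-person random streams derive from `root_seed + person_id`, so two
#' arms run with the same `root_seed` (or, equivalently, the same `streams`
#' store) share all randomness (common random numbers).
#'
#' @inheritParams simulate_arm
#' @param econ [econ_params()].
#' @param keep_persons keep the per-person accrual data frame in the result?
#' @return A `scenario_result`; with `n_persons = 1` the standard errors are
#'   `NA` and flagged.
#' @export
run_scenario <- function(cohort, params, law, policy, econ, root_seed = 1L,
                         streams = NULL, keep_persons = FALSE) {
  if (is.null(cohort) || nrow(cohort) == 0L) {
    stop_field("cohort", "must contain at least one person")
  }
  comp <- simulate_arm(
    cohort, params, law, policy,
    discount_rate = econ$discount_rate, streams = streams, root_seed = root_seed
  )
  acc <- accrue_components(comp, econ)
  n <- nrow(acc)
  se_of <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
  res <- scenario_result(
    arm = if (policy$program_flag) "program" else "status_quo",
    mean_cost = mean(acc$discounted_cost),
    mean_life_expectancy = mean(acc$life_years),
    mean_qaly = mean(acc$discounted_qaly),
    n_persons = n,
    root_seed = as.integer(root_seed),
    se = c(
      cost = se_of(acc$discounted_cost),
      life_expectancy = se_of(acc$life_years),
      qaly = se_of(acc$discounted_qaly)
    ),
    components = comp,
    persons = if (keep_persons) acc else NULL
  )
  res$degenerate_n <- n == 1L
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> arm = %s (n = %d)\n", x$arm, x$n_persons))
  cat(sprintf(
    "  mean cost $%.2f | life expectancy %.2f y | QALY %.2f\n",
    x$mean_cost, x$mean_life_expectancy, x$mean_qaly
  ))
  if (!anyNA(x$se)) {
    cat(sprintf(
      "  MC SE: cost %.2f, LE %.4f, QALY %.4f\n",
      x$se[["cost"]], x$se[["life_expectancy"]], x$se[["qaly"]]
    ))
  }
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Deltas are program minus status quo. Quadrant rules: positive incremental
#' QALYs at non-positive incremental cost is dominance of the program
#' (`DOMINANT`); non-positive QALYs at non-negative cost (not both zero) is
#' `DOMINATED`; the usual northeast quadrant reports
#' `ICER = delta_cost / delta_qaly` and is cost-effective when the ICER does
#' not exceed the willingness-to-pay threshold (the boundary counts as
#' cost-effective); the southwest quadrant (cheaper and less effective)
#' reports the ratio with a `SOUTHWEST` flag and is cost-effective when the
#' savings per QALY forgone are at least the threshold. Identical arms are
#' flagged `NO_DIFFERENCE`.
#'
#' @param program,status_quo `scenario_result`s from the same cohort and
#'   root seed (or hand-built via [scenario_result()]).
#' @param threshold willingness-to-pay threshold in USD per QALY (default
#'   50000).
#' @return An object of class `cea_comparison` with unrounded deltas, the
#'   ICER (or dominance label in `$flag`), and the threshold decision.
#' @export
compare_scenarios <- function(program, status_quo, threshold = 50000) {
  stopifnot(inherits(program, "scenario_result"), inherits(status_quo, "scenario_result"))
  if (program$n_persons != status_quo$n_persons) {
    stop("arms were run on different cohort sizes", call. = FALSE)
  }
  if (!is.na(program$root_seed) && !is.na(status_quo$root_seed) &&
    program$root_seed != status_quo$root_seed) {
    stop("arms were run with different root seeds (no common random numbers)", call. = FALSE)
  }
  dc <- program$mean_cost - status_quo$mean_cost
  dle <- program$mean_life_expectancy - status_quo$mean_life_expectancy
  dq <- program$mean_qaly - status_quo$mean_qaly

  icer <- NA_real_
  if (dc == 0 && dq == 0) {
    flag <- "NO_DIFFERENCE"
    ce <- NA
  } else if (dq > 0 && dc <= 0) {
    flag <- "DOMINANT"
    ce <- TRUE
  } else if (dq <= 0 && dc >= 0) {
    flag <- "DOMINATED"
    ce <- FALSE
  } else if (dq > 0 && dc > 0) {
    flag <- "ICER"
    icer <- dc / dq
    ce <- icer <= threshold
  } else { # dq < 0 && dc < 0
    flag <- "SOUTHWEST"
    icer <- dc / dq
    ce <- icer >= threshold
  }

  structure(
    list(
      delta_cost = dc,
      delta_life_expectancy = dle,
      delta_qaly = dq,
      icer = icer,
      flag = flag,
      threshold = threshold,
      cost_effective = ce,
      program = program,
      status_quo = status_quo
    ),
    class = "cea_comparison"
  )
}

# Table-style display rounding: cents for costs, 2 decimals for LE/QALY,
# ICER to the cent. Internal arithmetic stays unrounded.
#' @noRd
comparison_table <- function(x) {
  df <- data.frame(
    arm = c("program", "status_quo", "incremental"),
    cost = round(c(x$program$mean_cost, x$status_quo$mean_cost, x$delta_cost), 2),
    life_expectancy = round(c(
      x$program$mean_life_expectancy, x$status_quo$mean_life_expectancy,
      x$delta_life_expectancy
    ), 2),
    qaly = round(c(x$program$mean_qaly, x$status_quo$mean_qaly, x$delta_qaly), 2),
    icer = c(if (is.na(x$icer)) NA_real_ else round(x$icer, 2), NA_real_, NA_real_)
  )
  df
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison>\n")
  print(comparison_table(x), row.names = FALSE)
  lab <- if (x$flag %in% c("ICER", "SOUTHWEST")) {
    sprintf("ICER = $%.2f per QALY%s", x$icer,
            if (x$flag == "SOUTHWEST") " (southwest quadrant)" else "")
  } else {
    x$flag
  }
  cat(sprintf(
    "  %s | threshold $%s/QALY | cost-effective: %s\n",
    lab, format(x$threshold, big.mark = ","), x$cost_effective
  ))
  invisible(x)
}
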