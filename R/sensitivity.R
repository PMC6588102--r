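# Two-way deterministic sensitivity analysis: program cost per participant
# by achieved three-year screening rate, with extraction of the
# willingness-to-pay frontier.
#
# The program charge enters per-person cost additively, once, at discount
# factor 1, so at a fixed screening rate the incremental cost is affine in
# the program cost: dC(cost) = dC0 + cost, with dC0 the incremental cost at
# zero program cost. One simulation per rate therefore yields the ICER at
# every cost on the grid analytically, and the frontier solves
# ICER = threshold exactly: cost* = threshold * dQALY - dC0.

# Largest program cost with ICER <= threshold at incremental QALYs dq and
# zero-program-cost incremental cost dc0; NA where dq <= 0 or no
# non-negative cost qualifies.
#' @noRd
frontier_cost_at <- function(dq, dc0, threshold) {
  out <- ifelse(dq > 0, threshold * dq - dc0, NA_real_)
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Two-way cost-effectiveness frontier
#'
#' For each screening rate on `rate_grid`, simulates the program arm once
#' (common random numbers against a single fixed status-quo run) with the
#' program charge set to zero, and computes the ICER for every program cost
#' on `cost_grid` from the affine-in-cost identity above. The frontier is,
#' per rate, the largest program cost per participant at which the program
#' remains cost-effective (ICER at most `threshold`), or `NA` where the
#' incremental QALYs are non-positive or no non-negative cost qualifies.
#'
#' @inheritParams run_scenario
#' @param policy_sq status-quo [screening_policy()].
#' @param policy_program program-arm [screening_policy()]; its
#'   `three_year_uptake` is replaced by each grid rate in turn.
#' @param rate_grid strictly increasing three-year uptake values in `[0, 1]`.
#' @param cost_grid strictly increasing program costs per participant
#'   (USD, >= 0).
#' @param threshold willingness-to-pay threshold (USD/QALY).
#' @return An object of class `frontier_result`: the grids, per-rate
#'   incremental QALYs and zero-cost incremental costs, the ICER surface and
#'   outcome-label matrix (rates x costs), and a `frontier` data frame with
#'   columns `rate`, `frontier_cost`, `delta_qaly`,
#'   `delta_cost_at_zero_program_cost`. Rates below the status-quo uptake
#'   are permitted but flagged in `$flagged_rates`.
#' @export
two_way_frontier <- function(cohort, params, law, policy_sq, policy_program,
                             econ, rate_grid, cost_grid, threshold = 50000,
                             root_seed = 1L, streams = NULL) {
  if (any(rate_grid < 0) || any(rate_grid > 1) || any(diff(rate_grid) <= 0) && length(rate_grid) > 1) {
    stop_field("rate_grid", "must be strictly increasing within [0, 1]")
  }
  if (any(cost_grid < 0) || (length(cost_grid) > 1 && any(diff(cost_grid) <= 0))) {
    stop_field("cost_grid", "must be strictly increasing and >= 0")
  }
  if (is.null(streams)) streams <- navsim_streams(root_seed, nrow(cohort), law$max_age)
  econ0 <- econ
  econ0$program_cost_per_participant <- 0

  sq_comp <- simulate_arm(cohort, params, law, policy_sq,
    discount_rate = econ$discount_rate, streams = streams
  )
  sq_acc <- accrue_components(sq_comp, econ0, program_arm = FALSE)

  n_r <- length(rate_grid)
  dq <- numeric(n_r)
  dc0 <- numeric(n_r)
  dly <- numeric(n_r)
  for (i in seq_len(n_r)) {
    pol <- policy_program
    pol$three_year_uptake <- rate_grid[i]
    comp <- simulate_arm(cohort, params, law, pol,
      discount_rate = econ$discount_rate, streams = streams
    )
    acc <- accrue_components(comp, econ0, program_arm = FALSE) # zero program cost
    dq[i] <- mean(acc$discounted_qaly) - mean(sq_acc$discounted_qaly)
    dc0[i] <- mean(acc$discounted_cost) - mean(sq_acc$discounted_cost)
    dly[i] <- mean(acc$life_years) - mean(sq_acc$life_years)
  }

  icer <- outer(seq_len(n_r), seq_along(cost_grid), function(i, j) {
    ifelse(dq[i] != 0, (dc0[i] + cost_grid[j]) / dq[i], NA_real_)
  })
  outcome <- outer(seq_len(n_r), seq_along(cost_grid), function(i, j) {
    dc <- dc0[i] + cost_grid[j]
    ifelse(dq[i] == 0 & dc == 0, "NO_DIFFERENCE",
      ifelse(dq[i] > 0 & dc <= 0, "DOMINANT",
        ifelse(dq[i] <= 0 & dc >= 0, "DOMINATED",
          ifelse(dq[i] > 0, "ICER", "SOUTHWEST")
        )
      )
    )
  })

  frontier_cost <- frontier_cost_at(dq, dc0, threshold)

  structure(
    list(
      rate_grid = rate_grid,
      cost_grid = cost_grid,
      delta_qaly = dq,
      delta_cost0 = dc0,
      delta_life_expectancy = dly,
      icer_surface = icer,
      outcome = outcome,
      frontier = data.frame(
        rate = rate_grid,
        frontier_cost = frontier_cost,
        delta_qaly = dq,
        delta_cost_at_zero_program_cost = dc0
      ),
      threshold = threshold,
      status_quo_uptake = policy_sq$three_year_uptake,
      flagged_rates = rate_grid[rate_grid < policy_sq$three_year_uptake],
      root_seed = as.integer(root_seed),
      n_persons = nrow(cohort),
      boundary_convention = "ICER equal to the threshold counts as cost-effective"
    ),
    class = "frontier_result"
  )
}

#' Is a (rate, cost) point cost-effective?
#'
#' @param rate achieved three-year screening rate.
#' @param cost program cost per participant (USD).
#' @param frontier a `frontier_result`.
#' @return `TRUE` iff `cost` does not exceed the frontier cost at the
#'   nearest-not-exceeding grid rate (a point exactly on the frontier, where
#'   the ICER equals the threshold, counts as cost-effective).
#' @export
is_cost_effective <- function(rate, cost, frontier) {
  stopifnot(inherits(frontier, "frontier_result"))
  if (rate < min(frontier$rate_grid) || rate > max(frontier$rate_grid) ||
    cost < min(frontier$cost_grid) || cost > max(frontier$cost_grid)) {
    stop_field("(rate, cost)", "point lies outside the evaluated grid hull")
  }
  i <- max(which(frontier$rate_grid <= rate))
  fc <- frontier$frontier$frontier_cost[i]
  !is.na(fc) && cost <= fc
}

#' @export
print.frontier_result <- function(x, ...) {
  cat(sprintf(
    "<frontier_result> %d rates x %d costs, threshold $%s/QALY (n = %d per arm)\n",
    length(x$rate_grid), length(x$cost_grid),
    format(x$threshold, big.mark = ","), x$n_persons
  ))
  print(utils::head(x$frontier, 5), row.names = FALSE)
  if (length(x$rate_grid) > 5) cat(sprintf("  ... %d more rates\n", length(x$rate_grid) - 5))
  invisible(x)
}
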