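# Calibration of free model parameters to published per-arm outcomes.
#
# The loss is a weighted sum of squared relative errors over per-arm target
# cells (cost, life expectancy, QALY for each arm). Three free parameters
# (treatment-cost scale, utility-decrement scale, program cost per
# participant) enter the accruals linearly, so for any candidate disease
# model they are profiled exactly by weighted least squares on the engine's
# per-person components; a derivative-free Nelder-Mead simplex (on a
# logit-box transform) searches only the remaining epidemiological scales.
# The profiled search has the same minimum as the joint search over all six
# parameters but is far better conditioned. With a fixed root seed and
# common random numbers the loss is a deterministic function of the
# parameters.

CAL_OUTER <- c(
  "onset_hazard_scale", "symptomatic_detection_scale", "excess_bc_mortality_scale"
)
CAL_INNER <- c(
  "treatment_cost_scale", "utility_decrement_scale", "program_cost_per_participant"
)

#' Default calibration target table
#'
#' Per-arm lifetime discounted cost (USD), undiscounted life expectancy
#' (years) and discounted QALYs for the program and status-quo arms, as
#' published for the evaluated navigation program.
#'
#' @return Data frame with columns `quantity`, `arm`, `value`, `weight`.
#' @export
default_calibration_targets <- function() {
  data.frame(
    quantity = rep(c("cost", "life_expectancy", "qaly"), 2),
    arm = rep(c("program", "status_quo"), each = 3),
    value = c(2632.90, 23.03, 14.09, 2508.10, 22.32, 14.05),
    weight = 1
  )
}

#' Calibration specification
#'
#' @param free_parameters character vector naming the free parameters, a
#'   subset of `onset_hazard_scale`, `symptomatic_detection_scale`,
#'   `excess_bc_mortality_scale`, `treatment_cost_scale`,
#'   `utility_decrement_scale`, `program_cost_per_participant`. The scale
#'   parameters multiply the corresponding stage maps of the base
#'   configuration.
#' @param bounds named list of `c(lower, upper)` bounds per free parameter;
#'   defaults keep all scaled probabilities strictly inside `[0, 1]`.
#' @param targets data frame of target cells (`quantity`, `arm`, `value`,
#'   `weight`); defaults to [default_calibration_targets()].
#' @param n_eval cohort size per loss evaluation.
#' @param n_confirm cohort size of the final confirmation run.
#' @param root_seed root seed shared by every evaluation (the loss is then
#'   deterministic in the parameters).
#' @param max_evaluations simplex iteration budget.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(free_parameters = c(CAL_OUTER, CAL_INNER),
                             bounds = NULL,
                             targets = default_calibration_targets(),
                             n_eval = 20000L,
                             n_confirm = 100000L,
                             root_seed = 1L,
                             max_evaluations = 150L) {
  default_bounds <- list(
    onset_hazard_scale = c(5e-4, 0.05),
    symptomatic_detection_scale = c(0.3, 1.6),
    excess_bc_mortality_scale = c(0.2, 3.0),
    treatment_cost_scale = c(0, 5),
    utility_decrement_scale = c(0, 2.2),
    program_cost_per_participant = c(0, 20000)
  )
  unknown <- setdiff(free_parameters, c(CAL_OUTER, CAL_INNER))
  if (length(unknown)) {
    stop_field("free_parameters", paste("unknown:", paste(unknown, collapse = ", ")))
  }
  if (is.null(bounds)) bounds <- default_bounds[free_parameters]
  for (nm in free_parameters) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop_field(sprintf("bounds$%s", nm), "must be finite and ordered (lower < upper)")
    }
  }
  stopifnot(is.data.frame(targets),
            all(c("quantity", "arm", "value", "weight") %in% names(targets)))
  if (!all(targets$quantity %in% c("cost", "life_expectancy", "qaly"))) {
    stop_field("targets$quantity", "must be cost, life_expectancy or qaly")
  }
  if (!all(targets$arm %in% c("program", "status_quo"))) {
    stop_field("targets$arm", "must be program or status_quo")
  }
  if (any(targets$weight <= 0)) stop_field("targets$weight", "must be > 0")
  structure(
    list(
      free_parameters = free_parameters,
      bounds = bounds,
      targets = targets,
      n_eval = as.integer(n_eval),
      n_confirm = as.integer(n_confirm),
      root_seed = as.integer(root_seed),
      max_evaluations = as.integer(max_evaluations)
    ),
    class = "calibration_spec"
  )
}

# Apply a named parameter vector (full six-parameter set; non-free entries
# fixed at 1 / config values) to the base nh and econ objects.
#' @noRd
apply_cal_params <- function(theta, nh, econ) {
  nh2 <- nh
  nh2$onset_hazard_scale <- theta[["onset_hazard_scale"]]
  nh2$symptomatic_detection_prob <-
    pmin(nh$symptomatic_detection_prob * theta[["symptomatic_detection_scale"]], 1)
  nh2$excess_bc_mortality <-
    pmin(nh$excess_bc_mortality * theta[["excess_bc_mortality_scale"]], 1)
  econ2 <- econ
  econ2$treatment_cost_by_stage <-
    econ$treatment_cost_by_stage * theta[["treatment_cost_scale"]]
  econ2$utility_decrement_by_stage <-
    pmin(econ$utility_decrement_by_stage * theta[["utility_decrement_scale"]],
         econ$utility_healthy)
  econ2$program_cost_per_participant <- theta[["program_cost_per_participant"]]
  list(nh = nh2, econ = econ2)
}

# Arm-level accrual components needed by the profiled loss.
#' @noRd
arm_moments <- function(comp, econ) {
  has_dx <- comp$stage_dx > 0L
  treat_base <- numeric(length(comp$ly))
  decr_base <- numeric(length(comp$ly))
  treat_base[has_dx] <- econ$treatment_cost_by_stage[comp$stage_dx[has_dx]]
  decr_base[has_dx] <- econ$utility_decrement_by_stage[comp$stage_dx[has_dx]]
  list(
    LE = mean(comp$ly),
    D = mean(comp$disc_ly), # discounted life years
    B = mean(decr_base * comp$disc_ly_dx), # base-decrement-weighted dx years
    F = mean(
      econ$mammogram_cost * comp$disc_screens +
        econ$false_positive_workup_cost * comp$disc_fp +
        econ$terminal_care_cost * comp$disc_terminal
    ),
    G = mean(treat_base * comp$disc_dx) # base treatment cost at diagnosis
  )
}

# Profile the linear parameters on arm moments; returns the solved values
# (clipped to bounds) and the per-cell achieved quantities.
#' @noRd
profile_linear <- function(mom, spec, econ, fixed) {
  tg <- spec$targets
  clip <- function(x, nm) {
    b <- spec$bounds[[nm]]
    if (is.null(b)) x else min(max(x, b[1]), b[2])
  }
  # utility decrement scale (QALY cells: Q = u_h * D - s_u * B)
  s_u <- fixed[["utility_decrement_scale"]]
  qt <- tg[tg$quantity == "qaly", ]
  if ("utility_decrement_scale" %in% spec$free_parameters && nrow(qt)) {
    num <- den <- 0
    for (k in seq_len(nrow(qt))) {
      m <- mom[[qt$arm[k]]]
      w <- qt$weight[k]; Tv <- qt$value[k]
      num <- num + w * m$B * (econ$utility_healthy * m$D - Tv) / Tv^2
      den <- den + w * m$B^2 / Tv^2
    }
    if (den > 0) s_u <- clip(num / den, "utility_decrement_scale")
  }
  # cost cells: C = F + s_t * G + pc * 1[program]
  s_t <- fixed[["treatment_cost_scale"]]
  pc <- fixed[["program_cost_per_participant"]]
  ct <- tg[tg$quantity == "cost", ]
  free_t <- "treatment_cost_scale" %in% spec$free_parameters
  free_p <- "program_cost_per_participant" %in% spec$free_parameters
  if (nrow(ct) && (free_t || free_p)) {
    # weighted least squares on the free subset of (s_t, pc)
    X <- NULL; y <- NULL; w <- NULL
    for (k in seq_len(nrow(ct))) {
      m <- mom[[ct$arm[k]]]
      P <- as.numeric(ct$arm[k] == "program")
      row <- c(if (free_t) m$G, if (free_p) P)
      resid0 <- ct$value[k] - m$F -
        (if (!free_t) s_t * m$G else 0) - (if (!free_p) pc * P else 0)
      X <- rbind(X, row); y <- c(y, resid0); w <- c(w, ct$weight[k] / ct$value[k]^2)
    }
    sol <- tryCatch(
      solve(crossprod(X * sqrt(w)), crossprod(X * sqrt(w), y * sqrt(w))),
      error = function(e) NULL
    )
    if (!is.null(sol)) {
      j <- 1L
      if (free_t) { s_t <- clip(sol[j], "treatment_cost_scale"); j <- j + 1L }
      if (free_p) pc <- clip(sol[j], "program_cost_per_participant")
      # re-solve pc alone if clipping s_t moved it (pc enters one cell only)
      if (free_t && free_p) {
        kp <- which(ct$arm == "program")
        if (length(kp) == 1L) {
          m <- mom[["program"]]
          pc <- clip(ct$value[kp] - m$F - s_t * m$G, "program_cost_per_participant")
        }
      }
    }
  }
  list(utility_decrement_scale = s_u, treatment_cost_scale = s_t,
       program_cost_per_participant = pc)
}

# Achieved target-cell values given arm moments and linear parameters.
#' @noRd
achieved_cells <- function(mom, targets, econ, lin) {
  vapply(seq_len(nrow(targets)), function(k) {
    m <- mom[[targets$arm[k]]]
    switch(targets$quantity[k],
      cost = m$F + lin$treatment_cost_scale * m$G +
        lin$program_cost_per_participant * (targets$arm[k] == "program"),
      life_expectancy = m$LE,
      qaly = econ$utility_healthy * m$D - lin$utility_decrement_scale * m$B
    )
  }, numeric(1))
}

#' @noRd
cal_loss <- function(achieved, targets) {
  if (any(!is.finite(achieved))) return(1e6)
  sum(targets$weight * ((achieved - targets$value) / targets$value)^2)
}

#' Calibrate free parameters to the target table
#'
#' Runs the two-arm simulation at `n_eval` persons per evaluation under
#' common random numbers with a fixed root seed, minimising the weighted sum
#' of squared relative errors over the target cells, then re-simulates both
#' arms at `n_confirm` persons with the best parameters (re-profiling the
#' linearly entering parameters exactly on the confirmation run) and reports
#' achieved-versus-target diagnostics.
#'
#' @param spec a [calibration_spec()].
#' @param config a `navsim_config` (see [load_config()]) supplying the base
#'   cohort ages, mortality law, disease model, screening arms and
#'   economics.
#' @return An object of class `calibration_result`: `best_parameters` (the
#'   six-parameter vector), calibrated `nh` and `econ` objects,
#'   `loss` (confirmation loss), `loss_trajectory` (best-so-far per
#'   evaluation), `achieved` table, `confirmation` (both `scenario_result`s
#'   and their `cea_comparison`), `n_evaluations` and `converged`.
#' @export
calibrate <- function(spec, config) {
  stopifnot(inherits(spec, "calibration_spec"), inherits(config, "navsim_config"))
  nh <- config$nh; econ <- config$econ; law <- config$law
  pol_sq <- config$policies$status_quo; pol_pr <- config$policies$program
  targets <- spec$targets

  base_theta <- c(
    onset_hazard_scale = nh$onset_hazard_scale,
    symptomatic_detection_scale = 1,
    excess_bc_mortality_scale = 1,
    treatment_cost_scale = 1,
    utility_decrement_scale = 1,
    program_cost_per_participant = econ$program_cost_per_participant
  )
  outer_free <- intersect(CAL_OUTER, spec$free_parameters)

  cs <- config$cohort_spec
  cohort <- generate_cohort(cohort_spec(
    spec$n_eval, cs$entry_age_min, cs$entry_age_max, cs$age_weights,
    seed = spec$root_seed + 1L
  ))
  streams <- navsim_streams(spec$root_seed, spec$n_eval, law$max_age)

  n_evals <- 0L
  best_loss <- Inf
  trajectory <- numeric(0)
  evaluate <- function(theta) {
    mdl <- apply_cal_params(theta, nh, econ)
    mom <- list(
      status_quo = arm_moments(
        simulate_arm(cohort, mdl$nh, law, pol_sq, econ$discount_rate, streams), econ
      ),
      program = arm_moments(
        simulate_arm(cohort, mdl$nh, law, pol_pr, econ$discount_rate, streams), econ
      )
    )
    lin <- profile_linear(mom, spec, econ, fixed = as.list(theta[CAL_INNER]))
    theta[names(lin)] <- unlist(lin)
    achieved <- achieved_cells(mom, targets, econ, lin)
    list(theta = theta, loss = cal_loss(achieved, targets), achieved = achieved)
  }

  if (length(outer_free)) {
    lo <- vapply(spec$bounds[outer_free], `[`, numeric(1), 1L)
    hi <- vapply(spec$bounds[outer_free], `[`, numeric(1), 2L)
    to_x <- function(z) lo + (hi - lo) * stats::plogis(z)
    x0 <- pmin(pmax(base_theta[outer_free], lo + 1e-9 * (hi - lo)), hi - 1e-9 * (hi - lo))
    z0 <- stats::qlogis((x0 - lo) / (hi - lo))
    best_theta <- base_theta
    fn <- function(z) {
      theta <- base_theta
      theta[outer_free] <- to_x(z)
      ev <- evaluate(theta)
      n_evals <<- n_evals + 1L
      if (ev$loss < best_loss) {
        best_loss <<- ev$loss
        best_theta <<- ev$theta
      }
      trajectory[n_evals] <<- best_loss
      ev$loss
    }
    if (length(outer_free) == 1L) {
      # golden-section search is the reliable derivative-free choice in 1-D
      stats::optimize(function(x) {
        theta <- base_theta
        theta[outer_free] <- x
        ev <- evaluate(theta)
        n_evals <<- n_evals + 1L
        if (ev$loss < best_loss) {
          best_loss <<- ev$loss
          best_theta <<- ev$theta
        }
        trajectory[n_evals] <<- best_loss
        ev$loss
      }, lower = lo, upper = hi, tol = (hi - lo) * 1e-6)
      converged <- TRUE
    } else {
      opt <- stats::optim(
        z0, fn,
        method = "Nelder-Mead",
        control = list(maxit = spec$max_evaluations, reltol = 1e-5)
      )
      converged <- opt$convergence == 0L
    }
    theta_best <- best_theta
  } else {
    ev <- evaluate(base_theta)
    n_evals <- 1L
    trajectory <- ev$loss
    theta_best <- ev$theta
    best_loss <- ev$loss
    converged <- TRUE
  }

  # confirmation run at n_confirm, exact re-profiling of linear parameters
  cohort_c <- generate_cohort(cohort_spec(
    spec$n_confirm, cs$entry_age_min, cs$entry_age_max, cs$age_weights,
    seed = spec$root_seed + 1L
  ))
  streams_c <- navsim_streams(spec$root_seed, spec$n_confirm, law$max_age)
  mdl <- apply_cal_params(theta_best, nh, econ)
  comp_sq <- simulate_arm(cohort_c, mdl$nh, law, pol_sq, econ$discount_rate, streams_c)
  comp_pr <- simulate_arm(cohort_c, mdl$nh, law, pol_pr, econ$discount_rate, streams_c)
  mom_c <- list(status_quo = arm_moments(comp_sq, econ),
                program = arm_moments(comp_pr, econ))
  lin <- profile_linear(mom_c, spec, econ, fixed = as.list(theta_best[CAL_INNER]))
  theta_best[names(lin)] <- unlist(lin)
  mdl <- apply_cal_params(theta_best, nh, econ)
  mdl$nh$provenance <- "calibrated"

  mk_result <- function(comp, pol) {
    acc <- accrue_components(comp, mdl$econ, program_arm = pol$program_flag)
    n <- nrow(acc)
    scenario_result(
      arm = if (pol$program_flag) "program" else "status_quo",
      mean_cost = mean(acc$discounted_cost),
      mean_life_expectancy = mean(acc$life_years),
      mean_qaly = mean(acc$discounted_qaly),
      n_persons = n, root_seed = spec$root_seed,
      se = c(
        cost = stats::sd(acc$discounted_cost) / sqrt(n),
        life_expectancy = stats::sd(acc$life_years) / sqrt(n),
        qaly = stats::sd(acc$discounted_qaly) / sqrt(n)
      ),
      components = comp
    )
  }
  res_sq <- mk_result(comp_sq, pol_sq)
  res_pr <- mk_result(comp_pr, pol_pr)
  comparison <- compare_scenarios(res_pr, res_sq, threshold = config$cea$threshold)

  achieved <- achieved_cells(mom_c, targets, econ, lin)
  achieved_tbl <- data.frame(
    quantity = targets$quantity, arm = targets$arm,
    target = targets$value, achieved = achieved,
    rel_error = (achieved - targets$value) / targets$value
  )
  structure(
    list(
      best_parameters = theta_best,
      nh = mdl$nh,
      econ = mdl$econ,
      loss = cal_loss(achieved, targets),
      loss_trajectory = trajectory,
      n_evaluations = n_evals,
      converged = converged,
      achieved = achieved_tbl,
      confirmation = list(
        status_quo = res_sq, program = res_pr, comparison = comparison
      ),
      spec = spec
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> %d evaluations, converged = %s, confirmation loss %.3g\n",
    x$n_evaluations, x$converged, x$loss
  ))
  print(
    cbind(
      x$achieved[, c("quantity", "arm", "target")],
      achieved = round(x$achieved$achieved, 3),
      rel_error = sprintf("%+.2f%%", 100 * x$achieved$rel_error)
    ),
    row.names = FALSE
  )
  cat("best parameters:\n")
  print(round(x$best_parameters, 5))
  invisible(x)
}
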