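# Lifetime cost and QALY accrual along a single simulated life course.
#
# Reference implementation working directly off a life_course record; the
# cohort engine accrues the same quantities vectorized (see engine.R), and
# the test suite holds the two routes equal.

#' Discount factor
#'
#' @param years_from_entry non-negative time since cohort entry (years).
#' @param rate annual discount rate (>= 0), default 0.03.
#' @return `(1 + rate)^(-years_from_entry)`.
#' @export
discount_factor <- function(years_from_entry, rate = 0.03) {
  if (any(years_from_entry < 0)) stop_field("years_from_entry", "must be >= 0")
  if (rate < 0) stop_field("rate", "must be >= 0")
  (1 + rate)^(-years_from_entry)
}

#' Accrue discounted lifetime costs and QALYs for one life course
#'
#' Applies the accounting conventions used throughout the package: annual
#' cycles with a half-cycle correction (the year of death is credited 0.5
#' life years), utilities weighted by health state with the stage-specific
#' decrement applying from the diagnosis year onward, event costs (screens,
#' false-positive work-ups, diagnosis-year treatment, terminal care)
#' discounted to entry, and — in the program arm only — the one-time program
#' charge at entry (discount factor 1). Life years are reported
#' undiscounted.
#'
#' @param record a `life_course` from [run_life_course()].
#' @param econ [econ_params()].
#' @param arm `"status_quo"` or `"program"`; the program charge applies only
#'   in the program arm.
#' @return An `accrual_result` list: `discounted_cost`, `discounted_qaly`,
#'   `life_years`.
#' @export
accrue <- function(record, econ, arm = c("status_quo", "program")) {
  arm <- match.arg(arm)
  stopifnot(inherits(record, "life_course"), inherits(econ, "econ_params"))
  if (is.na(record$age_at_death)) {
    stop("accrue() requires a complete record ending in a death state", call. = FALSE)
  }
  r <- econ$discount_rate
  stage_idx <- match(record$stage_at_diagnosis, STAGES) # NA if never diagnosed

  ages <- record$entry_age:record$age_at_death
  t_off <- ages - record$entry_age
  df <- discount_factor(t_off, r)
  ly_frac <- rep(1, length(ages))
  ly_frac[length(ages)] <- 0.5
  diagnosed <- !is.na(record$age_at_diagnosis) & ages >= record$age_at_diagnosis
  util <- ifelse(
    diagnosed,
    econ$utility_healthy - econ$utility_decrement_by_stage[stage_idx],
    econ$utility_healthy
  )
  life_years <- sum(ly_frac)
  qaly <- sum(ly_frac * util * df)

  ev <- record$events
  ev_df <- discount_factor(ev$age - record$entry_age, r)
  cost <- sum(ev_df[ev$event == "SCREEN_ATTEND"]) * econ$mammogram_cost +
    sum(ev_df[ev$event == "FALSE_POSITIVE"]) * econ$false_positive_workup_cost +
    sum(ev_df[ev$event == "DEATH_BC"]) * econ$terminal_care_cost
  dx <- ev$event %in% c("DETECT_SYMPTOMATIC", "DETECT_SCREEN")
  if (any(dx)) {
    cost <- cost + ev_df[dx] * econ$treatment_cost_by_stage[stage_idx]
  }
  if (arm == "program") cost <- cost + econ$program_cost_per_participant

  structure(
    list(
      discounted_cost = as.numeric(cost),
      discounted_qaly = qaly,
      life_years = life_years
    ),
    class = "accrual_result"
  )
}
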