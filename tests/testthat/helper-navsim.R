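# Shared fixtures, built in code at test time.

# A mortality law with no deaths before the absorbing cap: isolates the
# disease process in natural-history tests.
law_no_death <- function(max_age = 100L) {
  mortality_law(makeham_c = 0, gompertz_a = 0, max_age = max_age)
}

# Constant annual death probability q at every age (table law).
law_constant_q <- function(q, max_age = 120L) {
  mortality_law_from_table(
    data.frame(age = 0:max_age, annual_death_prob = q),
    max_age = max_age
  )
}

# Disease switched off entirely.
nh_no_disease <- function() nh_params(onset_hazard_scale = 0)

# No screening at all.
policy_none <- function(program_flag = FALSE) {
  screening_policy(
    three_year_uptake = 0, background_uptake = 0, program_flag = program_flag
  )
}

# Economics with utility 1, no decrements, no discounting, no costs:
# QALYs then equal life years exactly.
econ_identity <- function() {
  econ_params(
    discount_rate = 0, program_cost_per_participant = 0, mammogram_cost = 0,
    false_positive_workup_cost = 0,
    treatment_cost_by_stage = c(DCIS = 0, LOCAL = 0, REGIONAL = 0, DISTANT = 0),
    terminal_care_cost = 0, utility_healthy = 1,
    utility_decrement_by_stage = c(DCIS = 0, LOCAL = 0, REGIONAL = 0, DISTANT = 0)
  )
}

# Default-parameter bundle (uncalibrated placeholders) for engine-level tests.
default_bundle <- function() {
  list(
    nh = nh_params(),
    law = mortality_law(),
    policy_sq = screening_policy(three_year_uptake = 0.60, program_flag = FALSE),
    policy_pr = screening_policy(three_year_uptake = 0.80, program_flag = TRUE),
    econ = econ_params()
  )
}
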