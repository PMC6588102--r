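# Parameter containers for the disease model, screening policies, and
# economics, with the invariants enforced at construction time.

#' Natural-history parameters
#'
#' Annual-cycle transition parameters of the disease model. The onset hazard
#' at age `x` is `onset_hazard_scale * exp(onset_age_shape * (x - 60))`,
#' converted to an annual probability via `1 - exp(-h)`. New cancers begin
#' preclinical DCIS with probability `frac_onset_dcis`, otherwise
#' preclinical local. Shipped defaults are uncalibrated placeholders
#' (`provenance = "uncalibrated placeholder"`); [calibrate()] is the
#' sanctioned way to obtain a set reproducing published outcomes.
#'
#' @param onset_hazard_scale onset hazard at age 60 (per year); free,
#'   calibrated.
#' @param onset_age_shape log-hazard slope of onset per year of age.
#' @param frac_onset_dcis probability onset begins as preclinical DCIS.
#' @param progression named/ordered vector of per-year transition
#'   probabilities `c(dcis_to_local, local_to_regional, regional_to_distant)`.
#' @param symptomatic_detection_prob per-year probability of clinical
#'   (symptomatic) surfacing, one value per stage DCIS, LOCAL, REGIONAL,
#'   DISTANT; must strictly increase with stage.
#' @param excess_bc_mortality per-year excess breast-cancer death
#'   probability after diagnosis, by stage at diagnosis; strictly increasing
#'   with stage.
#' @param provenance free-text provenance tag carried into run manifests.
#' @return An object of class `nh_params`.
#' @export
nh_params <- function(onset_hazard_scale = 0.006,
                      onset_age_shape = 0.025,
                      frac_onset_dcis = 0.80,
                      progression = c(
                        dcis_to_local = 0.35,
                        local_to_regional = 0.32,
                        regional_to_distant = 0.30
                      ),
                      symptomatic_detection_prob = c(
                        DCIS = 0.04, LOCAL = 0.12, REGIONAL = 0.30, DISTANT = 0.60
                      ),
                      excess_bc_mortality = c(
                        DCIS = 0.002, LOCAL = 0.015, REGIONAL = 0.06, DISTANT = 0.30
                      ),
                      provenance = "uncalibrated placeholder") {
  if (!is.numeric(onset_hazard_scale) || onset_hazard_scale < 0) {
    stop_field("onset_hazard_scale", "must be >= 0")
  }
  if (!is.numeric(onset_age_shape)) stop_field("onset_age_shape", "must be numeric")
  check_prob(frac_onset_dcis, "frac_onset_dcis")
  if (length(progression) != 3L) {
    stop_field("progression", "needs 3 stage-transition probabilities")
  }
  check_prob(progression, "progression")
  for (nm in c("symptomatic_detection_prob", "excess_bc_mortality")) {
    v <- get(nm)
    if (length(v) != 4L) stop_field(nm, "needs one value per stage (4)")
    check_prob(v, nm)
    if (any(diff(v) <= 0)) {
      stop_field(nm, "must strictly increase with stage (DCIS < LOCAL < REGIONAL < DISTANT)")
    }
  }
  structure(
    list(
      onset_hazard_scale = onset_hazard_scale,
      onset_age_shape = onset_age_shape,
      frac_onset_dcis = frac_onset_dcis,
      progression = unname(progression),
      symptomatic_detection_prob = stats::setNames(unname(symptomatic_detection_prob), STAGES),
      excess_bc_mortality = stats::setNames(unname(excess_bc_mortality), STAGES),
      provenance = provenance
    ),
    class = "nh_params"
  )
}

# Annual onset probability at integer age.
#' @noRd
onset_prob <- function(nh, age) {
  1 - exp(-nh$onset_hazard_scale * exp(nh$onset_age_shape * (age - 60)))
}

#' Screening policy
#'
#' A scenario arm's mammography participation schedule plus test
#' characteristics. The three-year program window is interpreted
#' cumulatively: with probability `three_year_uptake` a woman receives
#' exactly one program-window screen, at a uniformly chosen year offset
#' within the window. After the window, routine rounds are scheduled every
#' `screening_interval_years` and attended independently with probability
#' `background_uptake`; both arms share the same background behaviour, so
#' arms differ only through the window uptake.
#'
#' @param three_year_uptake probability of at least one mammogram during the
#'   program window (status quo 0.60, navigation program 0.80).
#' @param program_window_years length of the program window (years, >= 1).
#' @param background_uptake per-round participation probability after the
#'   window.
#' @param screening_interval_years years between routine rounds.
#' @param sensitivity_by_stage mammography sensitivity per preclinical
#'   stage; non-decreasing with stage.
#' @param specificity mammography specificity (healthy women; a positive in
#'   a healthy woman is a false positive with work-up cost only).
#' @param program_flag `TRUE` for the intervention (navigation-program) arm.
#' @return An object of class `screening_policy`.
#' @export
screening_policy <- function(three_year_uptake,
                             program_window_years = 3L,
                             background_uptake = 0.60,
                             screening_interval_years = 2L,
                             sensitivity_by_stage = c(
                               DCIS = 0.75, LOCAL = 0.85, REGIONAL = 0.90, DISTANT = 0.95
                             ),
                             specificity = 0.92,
                             program_flag = FALSE) {
  check_prob(three_year_uptake, "three_year_uptake")
  check_prob(background_uptake, "background_uptake")
  check_prob(specificity, "specificity")
  program_window_years <- as.integer(program_window_years)
  if (is.na(program_window_years) || program_window_years < 1L) {
    stop_field("program_window_years", "must be >= 1")
  }
  screening_interval_years <- as.integer(screening_interval_years)
  if (is.na(screening_interval_years) || screening_interval_years < 1L) {
    stop_field("screening_interval_years", "must be >= 1")
  }
  if (length(sensitivity_by_stage) != 4L) {
    stop_field("sensitivity_by_stage", "needs one value per stage (4)")
  }
  check_prob(sensitivity_by_stage, "sensitivity_by_stage")
  if (any(diff(sensitivity_by_stage) < 0)) {
    stop_field("sensitivity_by_stage", "must be non-decreasing with stage")
  }
  structure(
    list(
      three_year_uptake = three_year_uptake,
      program_window_years = program_window_years,
      background_uptake = background_uptake,
      screening_interval_years = screening_interval_years,
      sensitivity_by_stage = stats::setNames(unname(sensitivity_by_stage), STAGES),
      specificity = specificity,
      program_flag = isTRUE(program_flag)
    ),
    class = "screening_policy"
  )
}

#' Economic parameters
#'
#' Costs and utilities accrued along a life course, all discounted to entry
#' at `discount_rate`. The program cost is a one-time per-participant charge
#' at entry, applied in the program arm only. Utility decrements apply from
#' the year of diagnosis onward (asymptomatic preclinical disease carries no
#' decrement); the realised annual utility after diagnosis at stage `s` is
#' `utility_healthy - utility_decrement_by_stage[s]`, which must stay
#' non-negative.
#'
#' @param discount_rate annual discount rate (default 0.03).
#' @param program_cost_per_participant USD, once at entry, program arm only;
#'   free, calibrated.
#' @param mammogram_cost USD per attended screen.
#' @param false_positive_workup_cost USD per false-positive work-up.
#' @param treatment_cost_by_stage USD at the diagnosis year, by stage at
#'   diagnosis; non-decreasing with stage.
#' @param terminal_care_cost USD in the year of breast-cancer death.
#' @param utility_healthy annual QALY weight while undiagnosed.
#' @param utility_decrement_by_stage annual QALY decrement after diagnosis,
#'   by stage at diagnosis; non-decreasing with stage.
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(discount_rate = 0.03,
                        program_cost_per_participant = 500,
                        mammogram_cost = 100,
                        false_positive_workup_cost = 250,
                        treatment_cost_by_stage = c(
                          DCIS = 12000, LOCAL = 22000, REGIONAL = 45000, DISTANT = 80000
                        ),
                        terminal_care_cost = 40000,
                        utility_healthy = 0.92,
                        utility_decrement_by_stage = c(
                          DCIS = 0.05, LOCAL = 0.10, REGIONAL = 0.20, DISTANT = 0.40
                        )) {
  if (!is.numeric(discount_rate) || discount_rate < 0) {
    stop_field("discount_rate", "must be >= 0")
  }
  for (nm in c(
    "program_cost_per_participant", "mammogram_cost",
    "false_positive_workup_cost", "terminal_care_cost"
  )) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop_field(nm, "must be a single cost >= 0")
    }
  }
  if (length(treatment_cost_by_stage) != 4L || any(treatment_cost_by_stage < 0)) {
    stop_field("treatment_cost_by_stage", "needs 4 non-negative stage costs")
  }
  if (any(diff(treatment_cost_by_stage) < 0)) {
    stop_field("treatment_cost_by_stage", "must be non-decreasing with stage")
  }
  check_prob(utility_healthy, "utility_healthy")
  if (length(utility_decrement_by_stage) != 4L) {
    stop_field("utility_decrement_by_stage", "needs one value per stage (4)")
  }
  check_prob(utility_decrement_by_stage, "utility_decrement_by_stage")
  if (any(diff(utility_decrement_by_stage) < 0)) {
    stop_field("utility_decrement_by_stage", "must be non-decreasing with stage")
  }
  if (any(utility_healthy - utility_decrement_by_stage < 0)) {
    stop_field("utility_decrement_by_stage", "post-diagnosis utility would be negative")
  }
  structure(
    list(
      discount_rate = discount_rate,
      program_cost_per_participant = program_cost_per_participant,
      mammogram_cost = mammogram_cost,
      false_positive_workup_cost = false_positive_workup_cost,
      treatment_cost_by_stage = stats::setNames(unname(treatment_cost_by_stage), STAGES),
      terminal_care_cost = terminal_care_cost,
      utility_healthy = utility_healthy,
      utility_decrement_by_stage = stats::setNames(unname(utility_decrement_by_stage), STAGES)
    ),
    class = "econ_params"
  )
}
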