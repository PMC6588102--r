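# Screening participation and test outcome mechanics.

#' Assign the ages at which a person attends screening
#'
#' With probability `three_year_uptake` the person receives exactly one
#' program-window screen at a uniformly chosen year offset in
#' `0..program_window_years - 1`; afterwards each routine round (every
#' `screening_interval_years`, starting the year the window closes) is
#' attended independently with probability `background_uptake`. Fully
#' deterministic given the person's stream.
#'
#' @param person a person state from [new_person()].
#' @param policy a [screening_policy()].
#' @param stream the person's [person_stream()].
#' @return Sorted integer vector of attendance ages (possibly empty).
#'   Attendance at ages the person does not live to see is simply never
#'   realised by the simulator.
#' @export
assign_screen_years <- function(person, policy, stream) {
  ages <- integer(0)
  if (stream$program_u < policy$three_year_uptake) {
    offset <- min(
      floor(stream$offset_u * policy$program_window_years),
      policy$program_window_years - 1L
    )
    ages <- person$entry_age + as.integer(offset)
  }
  bg_ages <- seq.int(
    person$entry_age + policy$program_window_years, stream$max_age,
    by = policy$screening_interval_years
  )
  for (a in bg_ages) {
    if (stream$u(CH_BG_ATTEND, a) < policy$background_uptake) {
      ages <- c(ages, as.integer(a))
    }
  }
  sort(ages[ages <= stream$max_age])
}

#' Resolve one attended screen
#'
#' A preclinical cancer at stage `s` is detected with probability
#' `sensitivity_by_stage[s]`, fixing the stage at diagnosis and setting the
#' detection mode to screen detection. A healthy attendee tests false
#' positive with probability `1 - specificity` (a diagnostic work-up cost
#' with no lasting utility consequence).
#'
#' @param person person state; must be undiagnosed and alive.
#' @param policy a [screening_policy()].
#' @param stream the person's [person_stream()].
#' @param age age at the screen (years).
#' @return List with the updated `person` and `outcome`, one of
#'   `"DETECTED"`, `"NOT_DETECTED"`, `"FALSE_POSITIVE"`, `"TRUE_NEGATIVE"`.
#' @export
screen_detect <- function(person, policy, stream, age) {
  if (person$state >= STATE_CLINICAL) {
    stop("screen_detect() called on a diagnosed or dead person", call. = FALSE)
  }
  if (person$state %in% STATE_PRECLIN) {
    if (stream$u(CH_SCREEN_SENS, age) < policy$sensitivity_by_stage[person$state]) {
      person$stage_at_diagnosis <- person$state
      person$state <- STATE_CLINICAL
      person$detection_mode <- MODE_SCREEN
      person$age_at_diagnosis <- as.integer(age)
      return(list(person = person, outcome = "DETECTED"))
    }
    return(list(person = person, outcome = "NOT_DETECTED"))
  }
  if (stream$u(CH_FALSE_POS, age) < 1 - policy$specificity) {
    return(list(person = person, outcome = "FALSE_POSITIVE"))
  }
  list(person = person, outcome = "TRUE_NEGATIVE")
}
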