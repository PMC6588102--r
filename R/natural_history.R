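# Scalar (per-person) reference engine for the annual-cycle disease model.
#
# This implementation favours clarity over speed and is the behavioural
# contract for the vectorized engine in engine.R: both consume the same
# per-person uniform draws, so a life course simulated here is identical,
# event for event, to the corresponding row of a cohort run.

#' @noRd
event_row <- function(age, event, stage = 0L, mode = MODE_NONE) {
  data.frame(
    age = as.integer(age), event = event,
    stage = stage_name(stage), detection_mode = MODE_NAMES[mode + 1L],
    stringsAsFactors = FALSE
  )
}

#' Advance one person by one annual cycle
#'
#' Applies, in this fixed order: (1) other-cause death draw; (2) onset draw
#' if healthy; (3) one preclinical stage-progression draw; (4) symptomatic
#' detection draw; (5) screening detection draw if a screen is attended this
#' year and the person is still undiagnosed; (6) breast-cancer death draw if
#' diagnosed. Steps apply to the state as updated by earlier steps within
#' the same cycle, and a person who dies at step (1) takes no further part
#' in the cycle.
#'
#' @param person person state ([new_person()]); must not be dead.
#' @param age current age in completed years.
#' @param params [nh_params()].
#' @param law [mortality_law()].
#' @param screen_this_year whether the person attends a screen this cycle
#'   (see [assign_screen_years()]).
#' @param policy [screening_policy()].
#' @param stream the person's [person_stream()].
#' @return List with updated `person` and an `events` data frame
#'   (columns `age`, `event`, `stage`, `detection_mode`).
#' @export
step_person_year <- function(person, age, params, law, screen_this_year,
                             policy, stream) {
  if (person$state %in% c(STATE_DEAD_BC, STATE_DEAD_OTHER)) {
    stop("step_person_year() called on a dead person", call. = FALSE)
  }
  age <- as.integer(age)
  events <- list()

  # (1) other-cause death
  if (stream$u(CH_DEATH_OTHER, age) < annual_death_prob(age, law)) {
    person$state <- STATE_DEAD_OTHER
    person$age_at_death <- age
    return(list(person = person, events = event_row(age, "DEATH_OTHER")))
  }

  # (2) onset
  if (person$state == STATE_HEALTHY &&
    stream$u(CH_ONSET, age) < onset_prob(params, age)) {
    person$state <- if (stream$u(CH_ONSET_TYPE, age) < params$frac_onset_dcis) 1L else 2L
    person$age_at_onset <- age
    events <- c(events, list(event_row(age, "ONSET", person$state)))
  }

  # (3) at most one stage progression per cycle
  if (person$state %in% 1:3 &&
    stream$u(CH_PROGRESSION, age) < params$progression[person$state]) {
    person$state <- person$state + 1L
    events <- c(events, list(event_row(age, "PROGRESS", person$state)))
  }

  # (4) symptomatic (clinical) surfacing
  if (person$state %in% STATE_PRECLIN &&
    stream$u(CH_SYMPTOMATIC, age) < params$symptomatic_detection_prob[person$state]) {
    person$stage_at_diagnosis <- person$state
    person$state <- STATE_CLINICAL
    person$detection_mode <- MODE_SYMPTOMATIC
    person$age_at_diagnosis <- age
    events <- c(events, list(event_row(
      age, "DETECT_SYMPTOMATIC", person$stage_at_diagnosis, MODE_SYMPTOMATIC
    )))
  }

  # (5) screening
  if (screen_this_year && person$state < STATE_CLINICAL) {
    events <- c(events, list(event_row(age, "SCREEN_ATTEND")))
    res <- screen_detect(person, policy, stream, age)
    person <- res$person
    if (res$outcome == "DETECTED") {
      events <- c(events, list(event_row(
        age, "DETECT_SCREEN", person$stage_at_diagnosis, MODE_SCREEN
      )))
    } else if (res$outcome == "FALSE_POSITIVE") {
      events <- c(events, list(event_row(age, "FALSE_POSITIVE")))
    }
  }

  # (6) breast-cancer death
  if (person$state == STATE_CLINICAL &&
    stream$u(CH_DEATH_BC, age) < params$excess_bc_mortality[person$stage_at_diagnosis]) {
    person$state <- STATE_DEAD_BC
    person$age_at_death <- age
    events <- c(events, list(event_row(
      age, "DEATH_BC", person$stage_at_diagnosis, person$detection_mode
    )))
  }

  list(
    person = person,
    events = if (length(events)) do.call(rbind, events) else event_row(age, "NONE")[0, ]
  )
}

#' Simulate one complete life course
#'
#' Iterates [step_person_year()] from entry age until death (forced at
#' `max_age` by the absorbing mortality cap). Identical seed, person id and
#' policy always reproduce the identical record.
#'
#' @inheritParams step_person_year
#' @param stream the person's [person_stream()]; if `NULL`, derived from
#'   `root_seed` and the person id.
#' @param root_seed root seed used when `stream` is `NULL`.
#' @return An object of class `life_course`: the final person state plus the
#'   full event history and attended screen ages.
#' @export
run_life_course <- function(person, params, law, policy, stream = NULL,
                            root_seed = 1L) {
  if (person$state != STATE_HEALTHY) {
    stop("run_life_course() expects a person in HEALTHY state at entry", call. = FALSE)
  }
  if (is.null(stream)) {
    stream <- person_stream(root_seed, person$person_id, law$max_age)
  }
  screen_ages <- assign_screen_years(person, policy, stream)
  events <- list()
  for (age in person$entry_age:law$max_age) {
    step <- step_person_year(
      person, age, params, law,
      screen_this_year = age %in% screen_ages, policy = policy, stream = stream
    )
    person <- step$person
    if (nrow(step$events)) events <- c(events, list(step$events))
    if (person$state %in% c(STATE_DEAD_BC, STATE_DEAD_OTHER)) break
  }
  if (!person$state %in% c(STATE_DEAD_BC, STATE_DEAD_OTHER)) {
    # unreachable while q(max_age) = 1; loop guard per contract
    person$state <- STATE_DEAD_OTHER
    person$age_at_death <- law$max_age
    events <- c(events, list(event_row(law$max_age, "DEATH_OTHER")))
  }
  structure(
    list(
      person_id = person$person_id,
      entry_age = person$entry_age,
      state = STATE_NAMES[person$state + 1L],
      stage_at_diagnosis = stage_name(person$stage_at_diagnosis),
      detection_mode = MODE_NAMES[person$detection_mode + 1L],
      age_at_onset = person$age_at_onset,
      age_at_diagnosis = person$age_at_diagnosis,
      age_at_death = person$age_at_death,
      cause_of_death = if (person$state == STATE_DEAD_BC) "BC" else "OTHER",
      events = do.call(rbind, events),
      screen_ages = screen_ages
    ),
    class = "life_course"
  )
}

#' @export
print.life_course <- function(x, ...) {
  cat(sprintf(
    "<life_course> person %d: entry %d, death %d (%s)\n",
    x$person_id, x$entry_age, x$age_at_death, x$cause_of_death
  ))
  if (!is.na(x$age_at_diagnosis)) {
    cat(sprintf(
      "  diagnosed at %d, stage %s, mode %s\n",
      x$age_at_diagnosis, x$stage_at_diagnosis, x$detection_mode
    ))
  }
  cat(sprintf("  %d events, %d screens attended\n", nrow(x$events), length(x$screen_ages)))
  invisible(x)
}
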