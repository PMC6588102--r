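# Simulation cohort: the program's target population of women aged 40 and
# older, with a configurable discrete entry-age distribution.

#' Cohort specification
#'
#' @param n_persons number of simulated persons (>= 1).
#' @param entry_age_min youngest entry age (integer years, >= 40: the
#'   program targets women 40 and older).
#' @param entry_age_max oldest entry age (integer years).
#' @param age_weights discrete distribution over integer entry ages
#'   `entry_age_min..entry_age_max`; must sum to 1 (within 1e-9). Default is
#'   uniform.
#' @param seed RNG seed for cohort generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_persons, entry_age_min = 40L, entry_age_max = 70L,
                        age_weights = NULL, seed = 1L) {
  n_persons <- suppressWarnings(as.integer(n_persons))
  if (is.na(n_persons) || n_persons < 1L) stop_field("n_persons", "must be >= 1")
  entry_age_min <- as.integer(entry_age_min)
  entry_age_max <- as.integer(entry_age_max)
  if (is.na(entry_age_min) || entry_age_min < MIN_ENTRY_AGE) {
    stop_field("entry_age_min", "must be >= 40 (program targets women 40+)")
  }
  if (is.na(entry_age_max) || entry_age_max < entry_age_min) {
    stop_field("entry_age_max", "must be >= entry_age_min")
  }
  ages <- entry_age_min:entry_age_max
  if (is.null(age_weights)) age_weights <- rep(1 / length(ages), length(ages))
  if (length(age_weights) != length(ages)) {
    stop_field("age_weights", sprintf("must have one weight per age (%d)", length(ages)))
  }
  if (any(age_weights < 0) || abs(sum(age_weights) - 1) > 1e-9) {
    stop_field("age_weights", "must be non-negative and sum to 1 (within 1e-9)")
  }
  structure(
    list(
      n_persons = n_persons, entry_age_min = entry_age_min,
      entry_age_max = entry_age_max, age_weights = as.numeric(age_weights),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a simulation cohort
#'
#' Draws `n_persons` entry ages i.i.d. from the spec's age distribution.
#' All persons start healthy; the same spec (including seed) always yields
#' the identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `navsim_cohort` with columns `person_id`
#'   and `entry_age`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ages <- spec$entry_age_min:spec$entry_age_max
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(spec$seed)
  entry <- if (length(ages) == 1L) {
    rep(ages, spec$n_persons)
  } else {
    sample(ages, spec$n_persons, replace = TRUE, prob = spec$age_weights)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    data.frame(person_id = seq_len(spec$n_persons), entry_age = as.integer(entry)),
    class = c("navsim_cohort", "data.frame")
  )
}

#' Read a cohort CSV
#'
#' @param path CSV with header `person_id,entry_age` (UTF-8, comma-separated).
#' @return A `navsim_cohort` data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("person_id", "entry_age") %in% names(df))) {
    stop_field("cohort_csv", "needs columns `person_id` and `entry_age`")
  }
  if (any(df$entry_age < MIN_ENTRY_AGE)) {
    stop_field("entry_age", "all entry ages must be >= 40")
  }
  if (anyDuplicated(df$person_id)) stop_field("person_id", "must be unique")
  structure(
    data.frame(
      person_id = as.integer(df$person_id),
      entry_age = as.integer(df$entry_age)
    ),
    class = c("navsim_cohort", "data.frame")
  )
}

#' Write a cohort CSV
#'
#' @param cohort a `navsim_cohort` data frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(
    as.data.frame(cohort)[, c("person_id", "entry_age")],
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' New (healthy) person state
#'
#' @param person_id integer id.
#' @param entry_age entry age in years (>= 40).
#' @return A list representing one person's mutable simulation state.
#' @export
new_person <- function(person_id, entry_age) {
  entry_age <- as.integer(entry_age)
  if (is.na(entry_age) || entry_age < MIN_ENTRY_AGE) {
    stop_field("entry_age", "must be >= 40")
  }
  list(
    person_id = as.integer(person_id),
    entry_age = entry_age,
    state = STATE_HEALTHY,
    stage_at_diagnosis = 0L,
    detection_mode = MODE_NONE,
    age_at_onset = NA_integer_,
    age_at_diagnosis = NA_integer_,
    age_at_death = NA_integer_
  )
}
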