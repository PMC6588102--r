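# Per-person uniform streams.
#
# Every stochastic decision in the simulator consumes one pre-assigned
# uniform draw indexed by (person, decision channel, age). The draws for
# person i are the first `2 + 9 * n_ages` variates of R's Mersenne-Twister
# stream seeded with (root_seed + i) mod (2^31 - 1). Because the assignment
# is independent of simulation state, two scenario arms sharing a root seed
# share every draw: common random numbers are exact, and adding or removing
# persons never perturbs anyone else's trajectory.

# Decision channels, one draw per person-year each.
CH_DEATH_OTHER <- 1L
CH_ONSET <- 2L
CH_ONSET_TYPE <- 3L
CH_PROGRESSION <- 4L
CH_SYMPTOMATIC <- 5L
CH_SCREEN_SENS <- 6L
CH_FALSE_POS <- 7L
CH_DEATH_BC <- 8L
CH_BG_ATTEND <- 9L
N_CHANNELS <- 9L

MIN_ENTRY_AGE <- 40L

#' @noRd
person_seed <- function(root_seed, person_id) {
  as.integer((as.numeric(root_seed) + as.numeric(person_id)) %% 2147483647)
}

#' @noRd
n_age_slots <- function(max_age) as.integer(max_age) - MIN_ENTRY_AGE + 1L

#' @noRd
stream_length <- function(max_age) 2L + N_CHANNELS * n_age_slots(max_age)

# Column of the (channel, age) draw within a person's stream vector.
#' @noRd
stream_col <- function(channel, age, max_age) {
  2L + (channel - 1L) * n_age_slots(max_age) + (as.integer(age) - MIN_ENTRY_AGE + 1L)
}

#' Per-person random stream
#'
#' Deterministically derives the uniform draws governing one person's life
#' course from the root seed and the person id. Used by the scalar
#' reference engine ([run_life_course()]); [navsim_streams()] builds the
#' identical draws for a whole cohort at once.
#'
#' @param root_seed integer root seed of the run.
#' @param person_id integer person identifier (>= 1).
#' @param max_age absorbing maximum age of the simulation (years).
#' @return An object of class `person_stream` with elements `program_u` and
#'   `offset_u` (screening-participation draws) and `u(channel, age)`, a
#'   function returning the uniform for a decision channel at an age.
#' @export
person_stream <- function(root_seed, person_id, max_age = 100L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(person_seed(root_seed, person_id))
  draws <- stats::runif(stream_length(max_age))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    list(
      person_id = as.integer(person_id),
      max_age = as.integer(max_age),
      program_u = draws[1L],
      offset_u = draws[2L],
      u = function(channel, age) draws[stream_col(channel, age, max_age)]
    ),
    class = "person_stream"
  )
}

#' Cohort-wide uniform draw store
#'
#' Materialises the per-person streams of [person_stream()] for persons
#' `1..n_persons` into one matrix (rows = persons, columns = stream
#' positions). Scenario arms compared under common random numbers should be
#' run against the same store; the store can also be reused across repeated
#' evaluations (e.g. during calibration) because it depends only on
#' `root_seed`, `n_persons` and `max_age`.
#'
#' @inheritParams person_stream
#' @param n_persons number of persons (ids `1..n_persons`).
#' @return An object of class `navsim_streams`.
#' @export
navsim_streams <- function(root_seed, n_persons, max_age = 100L) {
  n_persons <- as.integer(n_persons)
  stopifnot(n_persons >= 1L)
  len <- stream_length(max_age)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  U <- matrix(0, nrow = len, ncol = n_persons)
  for (i in seq_len(n_persons)) {
    set.seed(person_seed(root_seed, i))
    U[, i] <- stats::runif(len)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    list(
      V = t(U), # n_persons x len; columns contiguous per stream position
      root_seed = as.integer(root_seed),
      n_persons = n_persons,
      max_age = as.integer(max_age)
    ),
    class = "navsim_streams"
  )
}

# Vector over all persons of the (channel, age) draw.
#' @noRd
streams_u <- function(streams, channel, age) {
  streams$V[, stream_col(channel, age, streams$max_age)]
}
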