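# Vectorized cohort engine.
#
# Simulates every person's annual-cycle life course simultaneously, one age
# at a time, consuming exactly the per-person draws of person_stream() (see
# rng.R), so results are identical to looping run_life_course() over the
# cohort. Economics are deliberately not applied here: the engine returns
# per-person epidemiological components (discounted life-years, screen
# counts, diagnosis/death discount factors, ...) from which accrue_components()
# computes costs and QALYs. Parameters that enter accrual linearly
# (treatment-cost scale, utility-decrement scale, program cost) can then be
# profiled exactly without re-simulating, which both the calibration and the
# frontier construction exploit.

#' Simulate one scenario arm over a cohort
#'
#' Low-level engine; most users want [run_scenario()]. Returns per-person
#' epidemiological components, not costs.
#'
#' @param cohort a `navsim_cohort` data frame.
#' @param params [nh_params()].
#' @param law [mortality_law()].
#' @param policy [screening_policy()].
#' @param discount_rate annual discount rate used for the discounted
#'   component columns.
#' @param streams a [navsim_streams()] store covering the cohort (built on
#'   demand from `root_seed` when `NULL`). Pass the same store to both arms
#'   for common random numbers.
#' @param root_seed root seed used when `streams` is `NULL`.
#' @return A list of per-person vectors: undiscounted half-cycle life years
#'   (`ly`), discounted life years (`disc_ly`), discounted life years lived
#'   diagnosed (`disc_ly_dx`), screen attendance counts and their discounted
#'   sum (`n_screens`, `disc_screens`), false positives (`n_fp`, `disc_fp`),
#'   discount factors at diagnosis and breast-cancer death (`disc_dx`,
#'   `disc_terminal`, zero when absent), `stage_dx` (0 = never diagnosed),
#'   `detection_mode`, event ages, and `cause` (`"BC"`/`"OTHER"`).
#' @export
simulate_arm <- function(cohort, params, law, policy, discount_rate = 0.03,
                         streams = NULL, root_seed = 1L) {
  stopifnot(inherits(params, "nh_params"), inherits(law, "mortality_law"),
            inherits(policy, "screening_policy"))
  n <- nrow(cohort)
  if (n < 1L) stop_field("cohort", "must contain at least one person")
  if (is.null(streams)) streams <- navsim_streams(root_seed, n, law$max_age)
  if (streams$n_persons < n || streams$max_age != law$max_age) {
    stop("stream store does not cover this cohort / mortality law", call. = FALSE)
  }
  entry <- as.integer(cohort$entry_age)
  if (any(entry < MIN_ENTRY_AGE) || any(entry > law$max_age)) {
    stop_field("entry_age", "must lie in [40, max_age]")
  }
  pid <- as.integer(cohort$person_id)
  if (anyNA(pid) || any(pid < 1L) || any(pid > streams$n_persons)) {
    stop_field("person_id", "must index into the stream store (1..n_persons)")
  }
  max_age <- law$max_age
  dfpow <- (1 + discount_rate)^(-(0:(max_age - MIN_ENTRY_AGE)))

  # streams are keyed by person id, so person draws do not depend on the
  # cohort's row order
  uni <- function(channel, age) streams$V[pid, stream_col(channel, age, max_age)]

  # program-window screening assignment (state-independent)
  prog_attend <- streams$V[pid, 1L] < policy$three_year_uptake
  offset <- pmin(
    floor(streams$V[pid, 2L] * policy$program_window_years),
    policy$program_window_years - 1L
  )
  prog_age <- entry + as.integer(offset)

  state <- integer(n)
  stage_dx <- integer(n)
  mode <- integer(n)
  alive <- rep(TRUE, n)
  ly <- numeric(n); disc_ly <- numeric(n); disc_ly_dx <- numeric(n)
  n_screens <- integer(n); disc_screens <- numeric(n)
  n_fp <- integer(n); disc_fp <- numeric(n)
  disc_dx <- numeric(n); disc_terminal <- numeric(n)
  age_onset <- rep(NA_integer_, n); age_dx <- rep(NA_integer_, n)
  age_death <- rep(NA_integer_, n)
  cause_bc <- logical(n)

  for (a in MIN_ENTRY_AGE:max_age) {
    active <- alive & entry <= a
    if (!any(active)) next
    t_off <- pmax(a - entry, 0L)
    dfv <- dfpow[t_off + 1L]
    q_a <- law$q[a + 1L]

    # (1) other-cause death
    die_o <- active & uni(CH_DEATH_OTHER, a) < q_a
    act <- active & !die_o

    # (2) onset
    on <- act & state == STATE_HEALTHY &
      uni(CH_ONSET, a) < onset_prob(params, a)
    if (any(on)) {
      dcis <- on & uni(CH_ONSET_TYPE, a) < params$frac_onset_dcis
      state[dcis] <- 1L
      state[on & !dcis] <- 2L
      age_onset[on] <- a
    }

    # (3) one stage-progression draw
    pre <- act & state >= 1L & state <= 3L
    if (any(pre)) {
      pp <- numeric(n)
      pp[pre] <- params$progression[state[pre]]
      adv <- pre & uni(CH_PROGRESSION, a) < pp
      state[adv] <- state[adv] + 1L
    }

    # (4) symptomatic surfacing
    pre <- act & state >= 1L & state <= 4L
    if (any(pre)) {
      ps <- numeric(n)
      ps[pre] <- params$symptomatic_detection_prob[state[pre]]
      sym <- pre & uni(CH_SYMPTOMATIC, a) < ps
      if (any(sym)) {
        stage_dx[sym] <- state[sym]
        state[sym] <- STATE_CLINICAL
        mode[sym] <- MODE_SYMPTOMATIC
        age_dx[sym] <- a
        disc_dx[sym] <- dfv[sym]
      }
    }

    # (5) screening (undiagnosed attendees only)
    t_ok <- a - entry # >= 0 for active persons
    bg_round <- t_ok >= policy$program_window_years &
      (t_ok - policy$program_window_years) %% policy$screening_interval_years == 0L
    attends <- (prog_attend & a == prog_age) |
      (bg_round & uni(CH_BG_ATTEND, a) < policy$background_uptake)
    scr <- act & state <= 4L & attends
    if (any(scr)) {
      n_screens[scr] <- n_screens[scr] + 1L
      disc_screens[scr] <- disc_screens[scr] + dfv[scr]
      det <- scr & state >= 1L
      if (any(det)) {
        pd <- numeric(n)
        pd[det] <- policy$sensitivity_by_stage[state[det]]
        det <- det & uni(CH_SCREEN_SENS, a) < pd
        if (any(det)) {
          stage_dx[det] <- state[det]
          state[det] <- STATE_CLINICAL
          mode[det] <- MODE_SCREEN
          age_dx[det] <- a
          disc_dx[det] <- dfv[det]
        }
      }
      fp <- scr & state == STATE_HEALTHY &
        uni(CH_FALSE_POS, a) < 1 - policy$specificity
      if (any(fp)) {
        n_fp[fp] <- n_fp[fp] + 1L
        disc_fp[fp] <- disc_fp[fp] + dfv[fp]
      }
    }

    # (6) breast-cancer death
    dxed <- act & state == STATE_CLINICAL
    die_b <- logical(n)
    if (any(dxed)) {
      pb <- numeric(n)
      pb[dxed] <- params$excess_bc_mortality[stage_dx[dxed]]
      die_b <- dxed & uni(CH_DEATH_BC, a) < pb
    }

    # accrual: half-cycle credit in the year of death
    died <- die_o | die_b
    lyf <- numeric(n)
    lyf[active] <- 1
    lyf[died] <- 0.5
    ly[active] <- ly[active] + lyf[active]
    disc_ly[active] <- disc_ly[active] + lyf[active] * dfv[active]
    dx_now <- active & state == STATE_CLINICAL # diagnosed by end of this cycle
    disc_ly_dx[dx_now] <- disc_ly_dx[dx_now] + lyf[dx_now] * dfv[dx_now]

    if (any(died)) {
      age_death[died] <- a
      cause_bc[die_b] <- TRUE
      disc_terminal[die_b] <- dfv[die_b]
      alive[died] <- FALSE
      state[die_o] <- STATE_DEAD_OTHER
      state[die_b] <- STATE_DEAD_BC
    }
  }

  list(
    person_id = cohort$person_id,
    entry_age = entry,
    ly = ly, disc_ly = disc_ly, disc_ly_dx = disc_ly_dx,
    n_screens = n_screens, disc_screens = disc_screens,
    n_fp = n_fp, disc_fp = disc_fp,
    disc_dx = disc_dx, disc_terminal = disc_terminal,
    stage_dx = stage_dx,
    detection_mode = MODE_NAMES[mode + 1L],
    age_onset = age_onset, age_dx = age_dx, age_death = age_death,
    cause = ifelse(cause_bc, "BC", "OTHER"),
    discount_rate = discount_rate,
    program_flag = policy$program_flag
  )
}

#' Costs and QALYs from engine components
#'
#' Applies the economic parameters to the per-person components returned by
#' [simulate_arm()]. Because treatment costs, utility decrements and the
#' program charge enter linearly, changing those parameters only requires
#' re-running this step, not the simulation.
#'
#' @param comp output of [simulate_arm()].
#' @param econ [econ_params()].
#' @param program_arm charge `program_cost_per_participant` at entry
#'   (discount factor 1)? Defaults to the arm's policy flag.
#' @return Data frame with `person_id`, `discounted_cost`,
#'   `discounted_qaly`, `life_years`.
#' @export
accrue_components <- function(comp, econ, program_arm = comp$program_flag) {
  stopifnot(inherits(econ, "econ_params"))
  has_dx <- comp$stage_dx > 0L
  treat <- numeric(length(comp$ly))
  decr <- numeric(length(comp$ly))
  treat[has_dx] <- econ$treatment_cost_by_stage[comp$stage_dx[has_dx]]
  decr[has_dx] <- econ$utility_decrement_by_stage[comp$stage_dx[has_dx]]
  cost <- econ$mammogram_cost * comp$disc_screens +
    econ$false_positive_workup_cost * comp$disc_fp +
    treat * comp$disc_dx +
    econ$terminal_care_cost * comp$disc_terminal +
    if (isTRUE(program_arm)) econ$program_cost_per_participant else 0
  qaly <- econ$utility_healthy * comp$disc_ly - decr * comp$disc_ly_dx
  data.frame(
    person_id = comp$person_id,
    discounted_cost = cost,
    discounted_qaly = qaly,
    life_years = comp$ly
  )
}
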