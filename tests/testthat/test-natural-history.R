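# Annual-cycle disease state machine.

test_that("all-zero hazards leave a healthy person untouched", {
  nh0 <- nh_no_disease()
  law <- law_no_death()
  pol <- policy_none()
  p <- new_person(1, 50)
  st <- person_stream(1, 1)
  step <- step_person_year(p, 50, nh0, law, FALSE, pol, st)
  expect_identical(step$person, p)
  expect_equal(nrow(step$events), 0)
})

test_that("stepping a dead person is a contract violation", {
  p <- new_person(1, 50)
  p$state <- 7L # DEAD_OTHER
  expect_error(
    step_person_year(p, 51, nh_params(), mortality_law(), FALSE,
                     policy_none(), person_stream(1, 1)),
    "dead"
  )
})

test_that("certain symptomatic surfacing diagnoses at the current stage", {
  nh <- nh_params(
    symptomatic_detection_prob = c(
      DCIS = 0.97, LOCAL = 0.98, REGIONAL = 0.99, DISTANT = 1.0
    ),
    # keep the same-cycle breast-cancer death draw from firing
    excess_bc_mortality = c(DCIS = 1e-9, LOCAL = 2e-9, REGIONAL = 3e-9, DISTANT = 4e-9)
  )
  p <- new_person(1, 60)
  p$state <- 4L # preclinical distant
  p$age_at_onset <- 55L
  st <- person_stream(3, 1)
  step <- step_person_year(p, 60, nh, law_no_death(), FALSE, policy_none(), st)
  expect_equal(step$person$state, 5L) # clinical
  expect_equal(step$person$stage_at_diagnosis, 4L)
  expect_equal(step$person$detection_mode, 2L) # symptomatic
  expect_true("DETECT_SYMPTOMATIC" %in% step$events$event)
  expect_equal(step$events$stage[step$events$event == "DETECT_SYMPTOMATIC"], "DISTANT")
})

test_that("first-cycle onset frequency matches the binomial oracle", {
  # annual onset probability p = 1 - exp(-scale) with a flat age shape
  p_target <- 0.01
  nh <- nh_params(onset_hazard_scale = -log(1 - p_target), onset_age_shape = 0)
  co <- generate_cohort(cohort_spec(10000, 40, 40, seed = 5))
  comp <- simulate_arm(co, nh, law_no_death(), policy_none(), 0, root_seed = 5)
  frac <- mean(!is.na(comp$age_onset) & comp$age_onset == 40L)
  se <- sqrt(p_target * (1 - p_target) / 10000)
  expect_lt(abs(frac - p_target), 3 * se)
})

test_that("a forced-progression cancer follows the hand-traced path", {
  # onset certain at entry and begins DCIS; progression certain each year;
  # symptomatic surfacing certain only at DISTANT; breast-cancer death
  # certain after diagnosis at DISTANT. Trace: age 40 onset DCIS + progress
  # to LOCAL; 41 progress to REGIONAL; 42 progress to DISTANT, surface,
  # die of breast cancer. (Residual draws have probability < 1e-8.)
  nh <- nh_params(
    onset_hazard_scale = 50, onset_age_shape = 0, frac_onset_dcis = 1,
    progression = c(1, 1, 1),
    symptomatic_detection_prob = c(DCIS = 0, LOCAL = 1e-9, REGIONAL = 2e-9, DISTANT = 1),
    excess_bc_mortality = c(DCIS = 1e-9, LOCAL = 2e-9, REGIONAL = 3e-9, DISTANT = 1)
  )
  for (seed in 1:3) {
    rec <- run_life_course(
      new_person(1, 40), nh, law_no_death(), policy_none(), root_seed = seed
    )
    expect_equal(rec$age_at_onset, 40L)
    expect_equal(rec$age_at_diagnosis, 42L)
    expect_equal(rec$age_at_death, 42L)
    expect_equal(rec$stage_at_diagnosis, "DISTANT")
    expect_equal(rec$cause_of_death, "BC")
    expect_equal(
      rec$events$event,
      c("ONSET", "PROGRESS", "PROGRESS", "PROGRESS", "DETECT_SYMPTOMATIC", "DEATH_BC")
    )
    expect_true(all(diff(rec$events$age) >= 0))
  }
})

test_that("every life course ends in exactly one death state with ordered ages", {
  b <- default_bundle()
  for (seed in c(2, 11)) {
    co <- generate_cohort(cohort_spec(2000, seed = seed))
    comp <- simulate_arm(co, b$nh, b$law, b$policy_pr, 0.03, root_seed = seed)
    expect_true(all(comp$cause %in% c("BC", "OTHER")))
    expect_true(all(!is.na(comp$age_death)))
    expect_true(all(comp$age_death >= comp$entry_age))
    has_on <- !is.na(comp$age_onset)
    expect_true(all(comp$age_onset[has_on] >= comp$entry_age[has_on]))
    has_dx <- !is.na(comp$age_dx)
    expect_true(all(comp$age_dx[has_dx] >= comp$age_onset[has_dx]))
    expect_true(all(comp$age_death[has_dx] >= comp$age_dx[has_dx]))
    # diagnosed iff a stage and a detection mode are on record
    expect_identical(has_dx, comp$stage_dx > 0L)
    expect_identical(has_dx, comp$detection_mode != "NONE")
    # breast-cancer death only after diagnosis
    expect_true(all(has_dx[comp$cause == "BC"]))
  }
})

test_that("scalar and vectorized engines agree person for person", {
  b <- default_bundle()
  n <- 150
  co <- generate_cohort(cohort_spec(n, seed = 42))
  for (pol in list(b$policy_sq, b$policy_pr)) {
    comp <- simulate_arm(co, b$nh, b$law, pol, 0.03, root_seed = 7)
    acc <- accrue_components(comp, b$econ, program_arm = pol$program_flag)
    for (i in seq_len(n)) {
      st <- person_stream(7, i, b$law$max_age)
      rec <- run_life_course(new_person(i, co$entry_age[i]), b$nh, b$law, pol, stream = st)
      a <- accrue(rec, b$econ, arm = if (pol$program_flag) "program" else "status_quo")
      expect_equal(a$life_years, comp$ly[i])
      expect_equal(a$discounted_cost, acc$discounted_cost[i])
      expect_equal(a$discounted_qaly, acc$discounted_qaly[i])
      expect_identical(rec$age_at_death, comp$age_death[i])
      expect_identical(
        match(rec$stage_at_diagnosis, c("DCIS", "LOCAL", "REGIONAL", "DISTANT"), nomatch = 0L),
        comp$stage_dx[i]
      )
    }
  }
})

test_that("raising distant-stage excess mortality never increases LE (CRN)", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(10000, seed = 4))
  st <- navsim_streams(4, 10000, b$law$max_age)
  nh_hi <- b$nh
  nh_hi$excess_bc_mortality["DISTANT"] <- 0.9
  lo <- simulate_arm(co, b$nh, b$law, b$policy_sq, 0, streams = st)
  hi <- simulate_arm(co, nh_hi, b$law, b$policy_sq, 0, streams = st)
  expect_true(all(hi$ly <= lo$ly)) # pathwise under common random numbers
  expect_lte(mean(hi$ly), mean(lo$ly))
})

test_that("disabling onset recovers the closed-form life expectancy", {
  law <- mortality_law()
  co <- generate_cohort(cohort_spec(30000, seed = 8))
  comp <- simulate_arm(co, nh_no_disease(), law, policy_none(), 0, root_seed = 8)
  analytic <- mean(expected_remaining_years(co$entry_age, law, half_cycle = TRUE))
  se <- sd(comp$ly) / sqrt(length(comp$ly))
  expect_lt(abs(mean(comp$ly) - analytic), 3 * se)
})

test_that("post-diagnosis survival decreases with stage at diagnosis", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(50000, seed = 6))
  comp <- simulate_arm(co, b$nh, b$law, b$policy_sq, 0, root_seed = 6)
  dxed <- comp$stage_dx > 0L
  surv <- comp$age_death[dxed] - comp$age_dx[dxed]
  means <- tapply(surv, comp$stage_dx[dxed], mean)
  expect_equal(length(means), 4)
  expect_true(all(diff(means) < 0)) # DCIS >= LOCAL >= REGIONAL >= DISTANT
})
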