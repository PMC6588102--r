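# Discounting and accrual conventions.

test_that("discount_factor has its closed-form values", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 0.970873786408, tolerance = 1e-10) # 1/1.03
  expect_equal(discount_factor(c(0, 5, 50), 0), rep(1, 3))
  expect_error(discount_factor(-1, 0.03), "years_from_entry")
})

test_that("half-cycle base cases accrue as the convention dictates", {
  nh0 <- nh_no_disease()
  pol <- policy_none()
  ec <- econ_identity()
  # death in the first cycle: 0.5 life years, 0.5 QALYs, zero cost
  rec1 <- run_life_course(new_person(1, 40), nh0, law_constant_q(1, 100), pol,
                          root_seed = 1)
  a1 <- accrue(rec1, ec, arm = "status_quo")
  expect_equal(a1$life_years, 0.5)
  expect_equal(a1$discounted_qaly, 0.5)
  expect_equal(a1$discounted_cost, 0)
  # two full years then death in year three: 2.5 life years
  tab <- data.frame(age = 0:100, annual_death_prob = c(rep(0, 42), rep(1, 59)))
  rec2 <- run_life_course(new_person(1, 40), nh0, mortality_law_from_table(tab, 100),
                          pol, root_seed = 1)
  expect_equal(rec2$age_at_death, 42L)
  a2 <- accrue(rec2, ec, arm = "status_quo")
  expect_equal(a2$life_years, 2.5)
  expect_equal(a2$discounted_qaly, 2.5)
})

test_that("the program arm differs by exactly the program charge at entry", {
  b <- default_bundle()
  rec <- run_life_course(new_person(3, 55), b$nh, b$law, b$policy_pr, root_seed = 3)
  sq <- accrue(rec, b$econ, arm = "status_quo")
  pr <- accrue(rec, b$econ, arm = "program")
  expect_equal(pr$discounted_cost - sq$discounted_cost,
               b$econ$program_cost_per_participant)
  expect_equal(pr$discounted_qaly, sq$discounted_qaly)
  expect_equal(pr$life_years, sq$life_years)
})

test_that("with utility 1 and zero discounting QALYs equal life years exactly", {
  co <- generate_cohort(cohort_spec(2000, seed = 14))
  b <- default_bundle()
  comp <- simulate_arm(co, b$nh, b$law, b$policy_sq, 0, root_seed = 14)
  acc <- accrue_components(comp, econ_identity(), program_arm = FALSE)
  expect_identical(acc$discounted_qaly, acc$life_years)
})

test_that("discounted QALYs are non-increasing in the discount rate", {
  b <- default_bundle()
  rec <- run_life_course(new_person(2, 45), b$nh, b$law, b$policy_sq, root_seed = 2)
  ec <- b$econ
  q <- vapply(c(0, 0.01, 0.03, 0.05, 0.10), function(r) {
    ec$discount_rate <- r
    accrue(rec, ec, arm = "status_quo")$discounted_qaly
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("cohort mean accruals are invariant to person ordering", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(1000, seed = 17))
  comp <- simulate_arm(co, b$nh, b$law, b$policy_sq, 0.03, root_seed = 17)
  acc <- accrue_components(comp, b$econ, program_arm = FALSE)
  perm <- c(seq(2, 1000, by = 2), seq(1, 999, by = 2)) # fixed interleave
  co2 <- co[perm, ]
  # per-person streams are keyed by person_id, so reordering rows must not
  # change anyone's accrual
  comp2 <- simulate_arm(co2, b$nh, b$law, b$policy_sq, 0.03, root_seed = 17)
  acc2 <- accrue_components(comp2, b$econ, program_arm = FALSE)
  expect_equal(acc2$discounted_cost[order(comp2$person_id)], acc$discounted_cost)
  expect_equal(mean(acc2$discounted_qaly), mean(acc$discounted_qaly))
})

test_that("economic invariants are enforced at construction", {
  expect_error(econ_params(discount_rate = -0.01), "discount_rate")
  expect_error(econ_params(mammogram_cost = -5), "mammogram_cost")
  expect_error(
    econ_params(utility_decrement_by_stage = c(DCIS = 0.9, LOCAL = 0.9, REGIONAL = 0.9, DISTANT = 0.95)),
    "utility_decrement_by_stage"
  )
})
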