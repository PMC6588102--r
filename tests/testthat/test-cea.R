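# Scenario runner and incremental comparison.

test_that("run_scenario is bit-identical under a repeated root seed", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(2000, seed = 10))
  r1 <- run_scenario(co, b$nh, b$law, b$policy_pr, b$econ, root_seed = 10)
  r2 <- run_scenario(co, b$nh, b$law, b$policy_pr, b$econ, root_seed = 10)
  expect_identical(r1$mean_cost, r2$mean_cost)
  expect_identical(r1$mean_qaly, r2$mean_qaly)
  expect_identical(r1$se, r2$se)
  expect_equal(r1$arm, "program")
})

test_that("with disease off and identity economics the oracle pins both LE and QALY", {
  co <- generate_cohort(cohort_spec(20000, seed = 20))
  law <- mortality_law()
  r <- run_scenario(co, nh_no_disease(), law, policy_none(), econ_identity(),
                    root_seed = 20)
  analytic <- mean(expected_remaining_years(co$entry_age, law, half_cycle = TRUE))
  expect_lt(abs(r$mean_life_expectancy - analytic),
            3 * r$se[["life_expectancy"]])
  expect_identical(r$mean_qaly, r$mean_life_expectancy)
})

test_that("a single-person cohort flags degenerate standard errors", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(1, 40, 40, seed = 1))
  r <- run_scenario(co, b$nh, b$law, b$policy_sq, b$econ, root_seed = 1)
  expect_true(r$degenerate_n)
  expect_true(all(is.na(r$se)))
  expect_error(run_scenario(co[0, ], b$nh, b$law, b$policy_sq, b$econ), "cohort")
})

test_that("published per-arm values reproduce the incremental table exactly", {
  pr <- scenario_result("program", 2632.90, 23.03, 14.09, n_persons = 100000)
  sq <- scenario_result("status_quo", 2508.10, 22.32, 14.05, n_persons = 100000)
  cmp <- compare_scenarios(pr, sq, threshold = 50000)
  expect_equal(cmp$delta_cost, 124.80, tolerance = 1e-9)
  expect_equal(cmp$delta_life_expectancy, 0.71, tolerance = 1e-9)
  expect_equal(cmp$delta_qaly, 0.04, tolerance = 1e-9)
  expect_equal(cmp$icer, 3120, tolerance = 1e-9)
  expect_true(cmp$cost_effective)
  expect_equal(cmp$flag, "ICER")
})

test_that("dominance quadrants and the no-difference case are labelled", {
  mk <- function(c, q) scenario_result("x", c, 20, q, n_persons = 10)
  dom <- compare_scenarios(mk(2490, 14.06), mk(2500, 14.05))
  expect_equal(dom$flag, "DOMINANT")
  expect_true(dom$cost_effective)
  dominated <- compare_scenarios(mk(2510, 14.04), mk(2500, 14.05))
  expect_equal(dominated$flag, "DOMINATED")
  expect_false(dominated$cost_effective)
  same <- compare_scenarios(mk(2500, 14.05), mk(2500, 14.05))
  expect_equal(same$flag, "NO_DIFFERENCE")
  expect_true(is.na(same$icer))
  sw <- compare_scenarios(mk(2400, 14.00), mk(2500, 14.05))
  expect_equal(sw$flag, "SOUTHWEST")
  expect_equal(sw$icer, -100 / -0.05)
})

test_that("swapping arms negates deltas and mirrors dominance", {
  a <- scenario_result("program", 2600, 23, 14.1, n_persons = 10)
  b <- scenario_result("status_quo", 2650, 22.9, 14.0, n_persons = 10)
  ab <- compare_scenarios(a, b)
  ba <- compare_scenarios(b, a)
  expect_equal(ab$delta_cost, -ba$delta_cost)
  expect_equal(ab$delta_qaly, -ba$delta_qaly)
  expect_equal(ab$flag, "DOMINANT")
  expect_equal(ba$flag, "DOMINATED")
})

test_that("mismatched cohorts or seeds are rejected", {
  a <- scenario_result("program", 1, 1, 1, n_persons = 10, root_seed = 1)
  b <- scenario_result("status_quo", 1, 1, 1, n_persons = 11, root_seed = 1)
  expect_error(compare_scenarios(a, b), "cohort")
  d <- scenario_result("status_quo", 1, 1, 1, n_persons = 10, root_seed = 2)
  expect_error(compare_scenarios(a, d), "seed")
})

test_that("equal policies under common random numbers give exactly zero deltas", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(3000, seed = 23))
  st <- navsim_streams(23, 3000, b$law$max_age)
  pol_same <- b$policy_pr
  pol_same$three_year_uptake <- b$policy_sq$three_year_uptake
  ec0 <- b$econ
  ec0$program_cost_per_participant <- 0
  r_sq <- run_scenario(co, b$nh, b$law, b$policy_sq, ec0, root_seed = 23, streams = st)
  r_pr <- run_scenario(co, b$nh, b$law, pol_same, ec0, root_seed = 23, streams = st)
  cmp <- compare_scenarios(r_pr, r_sq)
  expect_identical(cmp$delta_cost, 0)
  expect_identical(cmp$delta_qaly, 0)
  expect_identical(cmp$delta_life_expectancy, 0)
  expect_equal(cmp$flag, "NO_DIFFERENCE")
})
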