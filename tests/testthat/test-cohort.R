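# Cohort generation and background mortality.

test_that("generate_cohort honours the spec and is deterministic", {
  co <- generate_cohort(cohort_spec(100000, 40, 70, seed = 1))
  expect_equal(nrow(co), 100000)
  expect_true(all(co$entry_age >= 40))
  expect_true(all(co$entry_age <= 70))
  co2 <- generate_cohort(cohort_spec(100000, 40, 70, seed = 1))
  expect_identical(co, co2)
  expect_false(identical(co, generate_cohort(cohort_spec(100000, 40, 70, seed = 2))))
})

test_that("a point-mass age distribution yields that single age", {
  co <- generate_cohort(cohort_spec(1, 40, 40, seed = 9))
  expect_equal(nrow(co), 1)
  expect_equal(co$entry_age, 40L)
})

test_that("uniform 40-49 entry ages have the enumerated mean within 3 SE", {
  # discrete uniform on 40..49: mean 44.5, sd sqrt(8.25), by enumeration
  ages <- 40:49
  mu <- mean(ages)
  sdev <- sqrt(mean((ages - mu)^2))
  co <- generate_cohort(cohort_spec(10000, 40, 49, seed = 7))
  expect_lt(abs(mean(co$entry_age) - mu), 3 * sdev / sqrt(10000))
})

test_that("invalid cohort specs name the offending field", {
  expect_error(cohort_spec(0), "n_persons")
  expect_error(cohort_spec(10, entry_age_min = 39), "entry_age_min")
  expect_error(cohort_spec(10, 40, 41, age_weights = c(0.5, 0.4)), "age_weights")
  expect_error(cohort_spec(10, 40, 42, age_weights = c(0.5, 0.5)), "age_weights")
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(cohort_spec(50, seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, p)
  expect_identical(as.data.frame(read_cohort_csv(p)), as.data.frame(co))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("person_id,entry_age\n1,39", bad)
  expect_error(read_cohort_csv(bad), "entry_age")
})

test_that("annual_death_prob matches the closed form and the absorbing cap", {
  law0 <- mortality_law(makeham_c = 0, gompertz_a = 0)
  expect_equal(annual_death_prob(50, law0), 0)
  expect_equal(annual_death_prob(100, law0), 1) # cap, any law
  law <- mortality_law(makeham_c = 0.001, gompertz_a = 2e-5, gompertz_b = 0.1)
  # hand evaluation of 1 - exp(-(0.001 + 2e-5 * exp(0.1 * 60)))
  expect_equal(annual_death_prob(60, law), 0.00902758035295, tolerance = 1e-10)
  expect_error(annual_death_prob(101, law), "age")
})

test_that("expected_remaining_years has its closed-form values", {
  # constant hazard: geometric series (1 - q) / q (cap at 120 is negligible)
  lawc <- law_constant_q(0.2)
  expect_equal(expected_remaining_years(40, lawc), 0.8 / 0.2, tolerance = 1e-7)
  # certain death every year: zero remaining full years
  expect_equal(expected_remaining_years(40, law_constant_q(1)), 0)
  # deterministic survival to the cap
  expect_equal(expected_remaining_years(90, law_no_death(100)), 10)
  # half-cycle accounting adds exactly the death-year credit
  expect_equal(
    expected_remaining_years(90, law_no_death(100), half_cycle = TRUE), 10.5
  )
})

test_that("a life-table override reproduces tabulated probabilities", {
  tab <- data.frame(age = 0:100, annual_death_prob = rep(0.05, 101))
  law <- mortality_law_from_table(tab, max_age = 100)
  expect_equal(annual_death_prob(73, law), 0.05)
  expect_equal(annual_death_prob(100, law), 1)
  expect_error(
    mortality_law_from_table(data.frame(age = 40:60, annual_death_prob = 0.01)),
    "life_table"
  )
})
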