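# Two-way frontier construction.

test_that("the frontier solves threshold * dQALY - dC0, stub case included", {
  # ICER = threshold at cost* : with dQALY 0.04 and zero incremental cost at
  # zero program cost, cost* = 50000 * 0.04 = 2000
  expect_equal(navsim:::frontier_cost_at(0.04, 0, 50000), 2000)
  expect_equal(navsim:::frontier_cost_at(0.01, -50, 50000), 550)
  expect_true(is.na(navsim:::frontier_cost_at(0, 10, 50000))) # no QALY gain
  expect_true(is.na(navsim:::frontier_cost_at(-0.01, 0, 50000)))
  expect_true(is.na(navsim:::frontier_cost_at(0.001, 500, 50000))) # cost* < 0
})

test_that("frontier grid runs agree with direct re-simulation (affine shortcut)", {
  b <- default_bundle()
  n <- 2000
  co <- generate_cohort(cohort_spec(n, seed = 30))
  st <- navsim_streams(30, n, b$law$max_age)
  rate_grid <- c(0.60, 0.70, 0.80)
  cost_grid <- c(0, 500, 1500)
  fr <- two_way_frontier(co, b$nh, b$law, b$policy_sq, b$policy_pr, b$econ,
                         rate_grid, cost_grid, threshold = 50000, streams = st)
  ec0 <- b$econ
  ec0$program_cost_per_participant <- 0
  sq <- run_scenario(co, b$nh, b$law, b$policy_sq, ec0, streams = st)
  for (pt in list(c(1, 2), c(2, 1), c(2, 3), c(3, 1), c(3, 3))) {
    i <- pt[1]; j <- pt[2]
    pol <- b$policy_pr
    pol$three_year_uptake <- rate_grid[i]
    ec <- b$econ
    ec$program_cost_per_participant <- cost_grid[j]
    pr <- run_scenario(co, b$nh, b$law, pol, ec, streams = st)
    dq <- pr$mean_qaly - sq$mean_qaly
    dc <- pr$mean_cost - sq$mean_cost
    if (dq != 0) {
      expect_equal(fr$icer_surface[i, j], dc / dq, tolerance = 1e-9)
    }
  }
  # at the status-quo rate, CRN forces zero effect and therefore no frontier
  expect_equal(fr$delta_qaly[1], 0)
  expect_true(is.na(fr$frontier$frontier_cost[1]))
  # frontier costs obey the closed form at each rate
  expect_equal(
    fr$frontier$frontier_cost,
    navsim:::frontier_cost_at(fr$delta_qaly, fr$delta_cost0, 50000)
  )
})

test_that("is_cost_effective applies the inclusive boundary and grid hull", {
  fr <- structure(
    list(
      rate_grid = c(0.6, 0.7, 0.8),
      cost_grid = c(0, 1000, 2000),
      frontier = data.frame(
        rate = c(0.6, 0.7, 0.8),
        frontier_cost = c(NA, 800, 1600),
        delta_qaly = c(0, 0.016, 0.032),
        delta_cost_at_zero_program_cost = c(0, 0, 0)
      )
    ),
    class = "frontier_result"
  )
  expect_true(is_cost_effective(0.8, 0, fr)) # zero cost, positive QALY gain
  expect_true(is_cost_effective(0.8, 1600, fr)) # exactly on the frontier
  expect_false(is_cost_effective(0.8, 1601, fr)) # just above it
  expect_false(is_cost_effective(0.6, 0, fr)) # no QALY gain at this rate
  expect_true(is_cost_effective(0.75, 800, fr)) # nearest-not-exceeding rate 0.7
  expect_error(is_cost_effective(0.5, 100, fr), "grid")
  expect_error(is_cost_effective(0.7, 5000, fr), "grid")
})

test_that("rates below the status quo are flagged, not rejected", {
  b <- default_bundle()
  co <- generate_cohort(cohort_spec(500, seed = 33))
  st <- navsim_streams(33, 500, b$law$max_age)
  fr <- two_way_frontier(co, b$nh, b$law, b$policy_sq, b$policy_pr, b$econ,
                         rate_grid = c(0.50, 0.60), cost_grid = c(0, 100),
                         streams = st)
  expect_equal(fr$flagged_rates, 0.50)
  expect_error(
    two_way_frontier(co, b$nh, b$law, b$policy_sq, b$policy_pr, b$econ,
                     rate_grid = c(0.6, 0.6), cost_grid = c(0, 100), streams = st),
    "rate_grid"
  )
})
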