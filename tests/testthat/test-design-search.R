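# Design searches in this file run on shrunken grids (5-10% allocation,
# 0.5-1% marker steps) so the whole file stays fast; grid-optimality is
# checked by exhaustive re-scan at the same resolution.

test_that("expected cost follows the two-stage cost identity", {
  co <- cohort_spec(1000, 1, 3e5, 1, 10)
  al <- stage_allocation(0.5, 0.5, 0.01)
  expect_equal(expected_cost(co, al), 3.3e8)
  one <- stage_allocation(1, 1, 0.01)
  expect_equal(expected_cost(co, one), 1 * 3e5 * 1000 * 2)
  # increasing in the marker pass proportion
  costs <- vapply(c(0.01, 0.05, 0.2, 0.9), function(pm)
    expected_cost(co, stage_allocation(0.4, 0.6, pm)), numeric(1))
  expect_true(all(diff(costs) > 0))
})

test_that("cost advantage is the relative saving in percent", {
  co <- cohort_spec(1000, 1, 3e5, 1, 10)
  a <- evaluate_design(genetic_scenario(0.1, 0.1, 1.6), co,
                       stage_allocation(0.5, 0.5, 0.05))
  expect_equal(cost_advantage(a, a), 0)
  b <- a; b$expected_cost <- a$expected_cost / 2
  expect_equal(cost_advantage(a, b), 50)
})

co_small <- cohort_spec(500, 2, 1000, 1, 10)
sc_small <- calibrate_rel_risk(0.10, 0.20, co_small, 0.80)
g_small <- grid_spec(step_alloc = 0.05, step_markers = 0.005,
                     coarse_alloc = 0.2)

test_that("coarse-to-fine min-cost search equals the exhaustive scan", {
  a <- min_cost_design(sc_small, co_small, 0.75, grid = g_small)
  b <- min_cost_design(sc_small, co_small, 0.75, grid = g_small,
                       search = "exhaustive")
  expect_equal(coef(a), coef(b))
  expect_equal(a$evaluation$expected_cost, b$evaluation$expected_cost)
  expect_gte(a$evaluation$power_total, 0.75)
})

test_that("coarse-to-fine max-power search equals the exhaustive scan", {
  ref <- min_cost_design(sc_small, co_small, 0.75, grid = g_small)
  budget <- 0.6 * ref$evaluation$expected_cost
  a <- max_power_design(sc_small, co_small, budget, grid = g_small)
  b <- max_power_design(sc_small, co_small, budget, grid = g_small,
                        search = "exhaustive")
  expect_equal(coef(a), coef(b))
  expect_lte(a$evaluation$expected_cost, budget)
})

test_that("feasible sets nest: unrestricted <= restricted <= one-stage", {
  for (t in c(1, 4)) {
    co <- cohort_spec(500, t, 1000, 1, 10)
    sc <- calibrate_rel_risk(0.10, 0.20, co, 0.80)
    un <- min_cost_design(sc, co, 0.75, grid = g_small)
    re <- equality_restricted_min_cost(sc, co, 0.75, grid = g_small)
    one <- one_stage_design(sc, co)
    expect_lte(un$evaluation$expected_cost, re$evaluation$expected_cost)
    expect_lte(re$evaluation$expected_cost, one$expected_cost)
  }
})

test_that("symmetric cohorts give near-symmetric optimal allocations", {
  co <- cohort_spec(500, 1, 1000, 1, 10)
  sc <- calibrate_rel_risk(0.10, 0.20, co, 0.80)
  d <- min_cost_design(sc, co, 0.75, grid = g_small, search = "exhaustive")
  expect_lte(abs(d$allocation$pi_cases - d$allocation$pi_controls),
             g_small$step_alloc + 1e-12)
})

test_that("max-power is nondecreasing in the budget and hits the one-stage
           limit when unconstrained", {
  ref <- min_cost_design(sc_small, co_small, 0.75, grid = g_small)
  pw <- vapply(c(0.5, 0.75, 0.9, 1.0), function(f)
    max_power_design(sc_small, co_small,
                     f * ref$evaluation$expected_cost,
                     grid = g_small)$evaluation$power_total, numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
  one <- one_stage_design(sc_small, co_small)
  rich <- max_power_design(sc_small, co_small, one$expected_cost,
                           grid = g_small)
  expect_gte(rich$evaluation$power_total, ref$evaluation$power_total)
})

test_that("infeasible constraints are flagged rather than fabricated", {
  # power target above the one-stage ceiling
  un <- min_cost_design(sc_small, co_small, 0.9999, grid = g_small)
  expect_false(un$feasible)
  expect_true(is.null(un$allocation))
  # budget below every grid point
  mp <- max_power_design(sc_small, co_small, 1, grid = g_small)
  expect_false(mp$feasible)
})

test_that("fitted design object exposes coef/summary/simulate", {
  d <- min_cost_design(sc_small, co_small, 0.75, grid = g_small)
  cf <- coef(d)
  expect_named(cf, c("pi_cases", "pi_controls", "pi_markers"))
  s <- summary(d)
  expect_s3_class(s, "summary.twostage_design")
  expect_true(is.finite(s$advantage_vs_one_stage))
  sim <- simulate(d, nsim = 2000, seed = 5)
  expect_s3_class(sim, "twostage_sim")
  expect_lt(abs(sim$rejection_rate - d$evaluation$power_total),
            3 * sim$standard_error + 0.02)
})
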