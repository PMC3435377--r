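test_that("stage statistic moments: null case, antisymmetry, MC agreement", {
  m0 <- stage_statistic_moments(0.3, 0.3, 400, 900)
  expect_equal(m0$mean, 0)
  expect_equal(m0$variance, 1, tolerance = 1e-12)

  m <- stage_statistic_moments(0.55, 0.50, 500, 500)
  ms <- stage_statistic_moments(0.50, 0.55, 500, 500)
  expect_equal(m$mean, -ms$mean, tolerance = 1e-12)
  expect_equal(m$variance, ms$variance, tolerance = 1e-12)

  set.seed(7)
  z <- mc_z_stats(0.55, 0.50, 500, 500, 1e5)
  se_mean <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - m$mean), 3 * se_mean + 0.01)
  se_var <- sd(z^2) / sqrt(length(z))  # conservative SE for the variance
  expect_lt(abs(var(z) - m$variance), 3 * se_var + 0.01)
})

test_that("stage-1 critical value inverts the null pass proportion", {
  expect_equal(stage1_critical(1), 0)
  expect_equal(stage1_critical(0.05), 1.959964, tolerance = 1e-6)
  for (pm in c(0.001, 0.0855, 0.3, 0.9)) {
    c1 <- stage1_critical(pm)
    expect_equal(2 * pnorm(c1, lower.tail = FALSE), pm, tolerance = 1e-12)
  }
  expect_error(stage1_critical(0), "pi_markers")
})

test_that("stage-1 power retrieves the pass rate under the null", {
  null_m <- structure(list(mean = 0, variance = 1), class = "stage_moments")
  expect_equal(stage1_power(null_m, stage1_critical(0.085)), 0.085,
               tolerance = 1e-12)
  big <- structure(list(mean = 30, variance = 1), class = "stage_moments")
  expect_gt(stage1_power(big, 5), 1 - 1e-9)
  m <- structure(list(mean = 5, variance = 1), class = "stage_moments")
  expect_equal(stage1_power(m, 1.96),
               pnorm(-1.96 - 5) + pnorm(1.96 - 5, lower.tail = FALSE),
               tolerance = 1e-14)
})

test_that("information weights normalize and reduce to sqrt(pi) splits", {
  # equal allocation of an equal cohort: w1 = sqrt(pi), w2 = sqrt(1 - pi)
  for (pi in c(0.2, 0.5, 0.65)) {
    w <- information_weights(0.3, pi * 1000, pi * 1000,
                             (1 - pi) * 1000, (1 - pi) * 1000)
    expect_equal(w$w1, sqrt(pi), tolerance = 1e-12)
    expect_equal(w$w2, sqrt(1 - pi), tolerance = 1e-12)
  }
  # swapped case/control sizes leave the harmonic information unchanged
  w <- information_weights(0.5, 300, 700, 700, 300)
  expect_equal(w$w1, sqrt(0.5), tolerance = 1e-12)
  expect_equal(w$w2, sqrt(0.5), tolerance = 1e-12)
  # one-stage degenerate
  w1s <- information_weights(0.3, 1000, 2000, 0, 0)
  expect_equal(c(w1s$w1, w1s$w2), c(1, 0))
  expect_error(information_weights(0.3, 0, 0, 0, 0), "degenerate")
  # normalization across unequal allocations
  for (piA in c(0.3, 0.7)) for (piU in c(0.2, 0.9)) {
    w <- information_weights(0.12, piA * 1000, piU * 8000,
                             (1 - piA) * 1000, (1 - piU) * 8000)
    expect_equal(w$w1^2 + w$w2^2, 1, tolerance = 1e-12)
  }
})

test_that("null double-rejection probability matches adaptive quadrature", {
  # degenerate joint threshold: the joint test never filters
  expect_lt(abs(null_double_rejection_prob(1.5, 0, 0.8, 0.6) -
                  2 * pnorm(1.5, lower.tail = FALSE)), 1e-6)
  # unfiltered stage 1: the joint statistic is standard normal
  expect_equal(null_double_rejection_prob(0, 1.959964, sqrt(0.5), sqrt(0.5)),
               0.05, tolerance = 1e-7)
  for (c1 in c(0.5, 1.72, 2.5))
    for (w1 in c(0.4, sqrt(0.5), 0.8))
      for (cj in c(1.5, 3, 5.2)) {
        w2 <- sqrt(1 - w1^2)
        want <- quad_double_rejection(c1, cj, w1, w2)
        # default step: midpoint-rule error is O(h^2), ~1e-7 at h = 0.005
        expect_lt(abs(null_double_rejection_prob(c1, cj, w1, w2) - want),
                  1e-7)
        # refined step: converges below 1e-9
        expect_lt(abs(null_double_rejection_prob(c1, cj, w1, w2,
                                                 step = 2e-4) - want),
                  1e-9)
      }
})

test_that("null double-rejection probability matches a bivariate MC", {
  set.seed(11)
  n <- 2e6
  z1 <- rnorm(n); z2 <- rnorm(n)
  emp <- mean(abs(z1) > 1.5 & abs(0.8 * z1 + 0.6 * z2) > 2.2)
  se <- sqrt(emp * (1 - emp) / n)
  expect_lt(abs(null_double_rejection_prob(1.5, 2.2, 0.8, 0.6) - emp),
            3 * se)
})

test_that("joint critical value round-trips the marker-wise error", {
  grid <- expand.grid(pm = c(0.01, 0.0855, 0.3),
                      w1 = c(0.5, sqrt(0.5), 0.9))
  for (i in seq_len(nrow(grid))) {
    c1 <- stage1_critical(grid$pm[i])
    w1 <- grid$w1[i]; w2 <- sqrt(1 - w1^2)
    for (alpha in c(1.6667e-7, 1e-3)) {
      cj <- joint_critical(c1, w1, w2, alpha)
      expect_lt(abs(null_double_rejection_prob(c1, cj, w1, w2) - alpha),
                1e-10)
    }
  }
})

test_that("joint critical value boundary and monotonicity", {
  c1 <- stage1_critical(0.05)
  w1 <- sqrt(0.5); w2 <- sqrt(0.5)
  # alpha equal to the stage-1 pass rate: the joint test is vacuous
  expect_equal(joint_critical(c1, w1, w2, 0.05), 0, tolerance = 1e-6)
  expect_error(joint_critical(c1, w1, w2, 0.10), "infeasible")
  cjs <- vapply(c(1e-6, 1e-4, 1e-2), function(a)
    joint_critical(c1, w1, w2, a), numeric(1))
  expect_true(all(diff(cjs) < 0))
})

test_that("joint power retrieves the type-I error under null moments", {
  null_m <- structure(list(mean = 0, variance = 1), class = "stage_moments")
  calib <- list(c1 = stage1_critical(0.05), w1 = sqrt(0.5), w2 = sqrt(0.5))
  calib$c_joint <- joint_critical(calib$c1, calib$w1, calib$w2, 1e-3)
  expect_equal(joint_power(null_m, null_m, calib), 1e-3, tolerance = 1e-8)
  far <- structure(list(mean = 40, variance = 1), class = "stage_moments")
  expect_gt(joint_power(far, far, calib), 1 - 1e-9)
})

test_that("design evaluation orders powers and handles the one-stage limit", {
  co <- small_cohort()
  sc <- genetic_scenario(0.10, 0.10, 1.5)
  ev <- evaluate_design(sc, co, stage_allocation(0.6, 0.4, 0.05))
  expect_lte(ev$power_total, ev$power_stage1)
  expect_gt(ev$expected_cost, 0)
  expect_equal(ev$calibration$w1^2 + ev$calibration$w2^2, 1,
               tolerance = 1e-12)

  one <- evaluate_design(sc, co, stage_allocation(1, 1, 0.05))
  direct <- one_stage_power(sc$case_freq, sc$control_freq,
                            co$n_cases, co$n_controls, co$alpha_marker)
  expect_equal(one$power_total, direct, tolerance = 1e-9)
  expect_equal(one$expected_cost,
               co$cost_stage1 * co$n_markers * (co$n_cases + co$n_controls))
})

test_that("total power is nondecreasing in the marker pass proportion", {
  co <- small_cohort(t = 8, alpha = 0.05, M = 1e4)
  sc <- genetic_scenario(0.10, 0.10, 1.5)
  pms <- c(0.005, 0.02, 0.08, 0.3, 1)
  pw <- vapply(pms, function(pm)
    evaluate_design(sc, co, stage_allocation(0.5, 0.3, pm))$power_total,
    numeric(1))
  expect_true(all(diff(pw) >= -1e-9))
})

test_that("equal allocation at t = 1 reproduces the sqrt(pi) weighting", {
  co <- focal_cohort(t = 1)
  sc <- genetic_scenario(0.10, 0.10, 1.6)
  for (pi in c(0.3, 0.5, 0.75)) {
    ev <- evaluate_design(sc, co, stage_allocation(pi, pi, 0.05))
    expect_equal(ev$calibration$w1, sqrt(pi), tolerance = 1e-12)
    expect_equal(ev$calibration$w2, sqrt(1 - pi), tolerance = 1e-12)
  }
})
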