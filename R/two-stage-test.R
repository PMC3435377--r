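#' Asymptotic moments of the stage-wise allele-frequency z-statistic
#'
#' The stage statistic compares estimated case and control allele
#' frequencies, standardized by the null pooled-variance standard error.
#' With \eqn{\bar p = (n_A p_A + n_U p_U)/(n_A + n_U)} and
#' \eqn{SE_0 = \sqrt{\bar p (1-\bar p)(1/(2 n_A) + 1/(2 n_U))}}, the
#' statistic is asymptotically normal with mean
#' \eqn{\mu = (p_A - p_U)/SE_0} and variance
#' \eqn{\sigma^2 = [p_A(1-p_A)/(2 n_A) + p_U(1-p_U)/(2 n_U)] / SE_0^2}
#' under the alternative; under the null it is standard normal.
#'
#' @param p_case,p_control Case and control risk-allele frequencies.
#' @param n_cases,n_controls Stage sample sizes (diploid individuals; may be
#'   fractional for analytic design evaluation).
#'
#' @return An object of class \code{stage_moments}: list with \code{mean}
#'   and \code{variance}.
#' @export
stage_statistic_moments <- function(p_case, p_control, n_cases, n_controls) {
  stopifnot(p_case > 0, p_case < 1, p_control > 0, p_control < 1)
  if (n_cases <= 0 || n_controls <= 0)
    stop("degenerate stage: both cases and controls are required")
  pbar <- (n_cases * p_case + n_controls * p_control) / (n_cases + n_controls)
  v0 <- pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls))
  v1 <- p_case * (1 - p_case) / (2 * n_cases) +
    p_control * (1 - p_control) / (2 * n_controls)
  structure(list(mean = (p_case - p_control) / sqrt(v0),
                 variance = v1 / v0),
            class = "stage_moments")
}

#' Stage-1 critical value from the marker pass proportion
#'
#' Two-sided standard-normal threshold such that, under the null, a
#' proportion \code{pi_markers} of markers is expected to pass to stage 2:
#' \eqn{P(|Z| > c_1) = \pi_{markers}}.
#'
#' @param pi_markers Expected null pass proportion, in (0, 1].
#' @return The critical value \eqn{c_1 \ge 0}; 0 when \code{pi_markers = 1}.
#' @export
stage1_critical <- function(pi_markers) {
  if (!is.finite(pi_markers) || pi_markers <= 0 || pi_markers > 1)
    stop("pi_markers must lie in (0, 1]")
  stats::qnorm(1 - pi_markers / 2)
}

#' Power of the stage-1 test
#'
#' Two-sided rejection probability of the stage-1 statistic with the given
#' asymptotic moments: \eqn{\Phi((-c_1-\mu)/\sigma) + 1 - \Phi((c_1-\mu)/\sigma)}.
#' Under the null this retrieves \code{pi_markers}.
#'
#' @param moments A \code{\link{stage_statistic_moments}} object.
#' @param critical Stage-1 critical value \eqn{c_1 \ge 0}.
#' @return A probability.
#' @export
stage1_power <- function(moments, critical) {
  s <- sqrt(moments$variance)
  stats::pnorm((-critical - moments$mean) / s) +
    stats::pnorm((critical - moments$mean) / s, lower.tail = FALSE)
}

#' Fisher-information stage weights
#'
#' Stage weights for the joint statistic, proportional to the square root of
#' each stage's null-model Fisher information
#' \eqn{I_k = 1/[\bar p(1-\bar p)(1/(2 n_{A,k}) + 1/(2 n_{U,k}))]}
#' (the reciprocal null variance of the stage's allele-frequency
#' difference), normalized so \eqn{w_1^2 + w_2^2 = 1}. A stage with zero
#' cases or zero controls carries no information and gets weight 0.
#'
#' @param p_bar Pooled null allele frequency (stage-invariant; computed from
#'   the whole cohort).
#' @param n_cases1,n_controls1,n_cases2,n_controls2 Stage-wise sample sizes.
#'
#' @return List with \code{w1}, \code{w2}, \code{info1}, \code{info2}.
#' @export
information_weights <- function(p_bar, n_cases1, n_controls1,
                                n_cases2, n_controls2) {
  stopifnot(p_bar > 0, p_bar < 1)
  info <- function(nA, nU) {
    if (nA <= 0 || nU <= 0) return(0)
    1 / (p_bar * (1 - p_bar) * (1 / (2 * nA) + 1 / (2 * nU)))
  }
  i1 <- info(n_cases1, n_controls1)
  i2 <- info(n_cases2, n_controls2)
  if (i1 + i2 <= 0) stop("degenerate design: both stages are empty")
  list(w1 = sqrt(i1 / (i1 + i2)), w2 = sqrt(i2 / (i1 + i2)),
       info1 = i1, info2 = i2)
}

# Midpoint-rule abscissae and interval width over [a, b] with nominal step h.
# The step is shrunk so that an integer number of panels tiles [a, b] exactly;
# the rule is exact at the domain edges, which matters because the stage-1
# rejection region has a hard boundary at c1.
midpoint_grid <- function(a, b, h) {
  if (b <= a) return(list(x = numeric(0), h = 0))
  n <- max(1L, ceiling((b - a) / h))
  h <- (b - a) / n
  list(x = a + (seq_len(n) - 0.5) * h, h = h)
}

# P(|w1 Z1 + w2 Z2| > cj | Z1 = z1) for Z2 ~ N(mean2, sd2^2), vectorized
# over z1. w2 = 0 is handled by the caller.
joint_tail_given_z1 <- function(z1, cj, w1, w2, mean2 = 0, sd2 = 1) {
  stats::pnorm((cj - w1 * z1) / w2, mean = mean2, sd = sd2,
               lower.tail = FALSE) +
    stats::pnorm((-cj - w1 * z1) / w2, mean = mean2, sd = sd2)
}

#' Null probability of rejection at both stages
#'
#' Probability, under the null (independent standard-normal stage
#' statistics), that a marker passes the stage-1 filter and is rejected by
#' the joint test:
#' \eqn{P(|Z_1| > c_1 \;\mathrm{and}\; |w_1 Z_1 + w_2 Z_2| > c_J)}.
#' Evaluated by midpoint-rule (rectangular) cubature of the conditional
#' normal tail over the stage-1 rejection region, truncated at |z1| = 8.
#'
#' @param c1 Stage-1 critical value.
#' @param c_joint Joint-test critical value.
#' @param w1,w2 Information weights with \eqn{w_1^2 + w_2^2 = 1}.
#' @param step Integration step in standard-normal units.
#' @return A probability.
#' @export
null_double_rejection_prob <- function(c1, c_joint, w1, w2, step = 0.005) {
  stopifnot(c1 >= 0, c_joint >= 0, w1 >= 0, w2 >= 0)
  if (w2 == 0) {
    thr <- max(c1, if (w1 > 0) c_joint / w1 else Inf)
    return(2 * stats::pnorm(thr, lower.tail = FALSE))
  }
  # symmetric in z1 under the null: integrate the upper region and double
  g <- midpoint_grid(c1, 8, step)
  if (length(g$x) == 0) return(0)
  2 * g$h * sum(stats::dnorm(g$x) * joint_tail_given_z1(g$x, c_joint, w1, w2))
}

#' Joint critical value by bisection
#'
#' Solves for the joint-test threshold \eqn{c_J} such that the null
#' probability of rejecting at both stages equals the marker-wise type-I
#' error: \code{null_double_rejection_prob(c1, cJ, w1, w2) = alpha_marker}.
#' The stage-1 filter must pass at least \code{alpha_marker} null mass
#' (\eqn{\pi_{markers} \ge \alpha_{marker}}), else no threshold exists.
#'
#' @inheritParams null_double_rejection_prob
#' @param alpha_marker Marker-wise type-I error rate.
#' @param tol Absolute probability residual at termination.
#' @return The joint critical value \eqn{c_J \ge 0}.
#' @export
joint_critical <- function(c1, w1, w2, alpha_marker, step = 0.005,
                           tol = 1e-12) {
  if (w2 == 0) {
    # joint statistic reduces to w1 Z1; direct normal quantile
    cj <- w1 * stats::qnorm(1 - alpha_marker / 2)
    if (2 * stats::pnorm(c1, lower.tail = FALSE) < alpha_marker)
      stop("infeasible threshold: stage-1 pass rate below the error budget")
    return(cj)
  }
  pass1 <- 2 * stats::pnorm(c1, lower.tail = FALSE)
  if (pass1 < alpha_marker)
    stop("infeasible threshold: stage-1 pass rate below the error budget")
  # precompute the stage-1 grid once; only c_joint moves during bisection
  g <- midpoint_grid(c1, 8, step)
  dens <- stats::dnorm(g$x)
  f <- function(cj)
    2 * g$h * sum(dens * joint_tail_given_z1(g$x, cj, w1, w2)) - alpha_marker
  lo <- 0; hi <- 10
  if (f(hi) > 0) stop("joint critical value exceeds bisection bracket")
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-10) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Analytic power of the two-stage joint analysis
#'
#' Probability under the alternative of passing stage 1 and rejecting with
#' the joint statistic,
#' \eqn{P(|Z_1| > c_1 \;\mathrm{and}\; |w_1 Z_1 + w_2 Z_2| > c_J)} with
#' \eqn{Z_k \sim N(\mu_k, \sigma_k^2)} independent, by midpoint-rule
#' cubature over the stage-1 rejection region (truncated at
#' \eqn{\mu_1 \pm 8\sigma_1}).
#'
#' @param moments1,moments2 Stage-wise \code{\link{stage_statistic_moments}}.
#' @param calibration A list with \code{c1}, \code{c_joint}, \code{w1},
#'   \code{w2} (see \code{\link{joint_calibration}}).
#' @param step Integration step, in stage-1 standard deviations.
#' @return The total power of the design, a probability.
#' @export
joint_power <- function(moments1, moments2, calibration, step = 0.005) {
  c1 <- calibration$c1; cj <- calibration$c_joint
  w1 <- calibration$w1; w2 <- calibration$w2
  mu1 <- moments1$mean; s1 <- sqrt(moments1$variance)
  if (w2 == 0) {
    thr <- max(c1, if (w1 > 0) cj / w1 else Inf)
    return(stats::pnorm((-thr - mu1) / s1) +
             stats::pnorm((thr - mu1) / s1, lower.tail = FALSE))
  }
  mu2 <- moments2$mean; s2 <- sqrt(moments2$variance)
  lo <- mu1 - 8 * s1; hi <- mu1 + 8 * s1
  h <- step * s1
  acc <- 0
  piece <- function(a, b) {
    g <- midpoint_grid(a, b, h)
    if (length(g$x) == 0) return(0)
    g$h * sum(stats::dnorm(g$x, mean = mu1, sd = s1) *
                joint_tail_given_z1(g$x, cj, w1, w2, mean2 = mu2, sd2 = s2))
  }
  acc <- piece(max(c1, lo), hi) + piece(lo, min(-c1, hi))
  min(1, acc)
}

#' Calibrate the critical values and weights of a two-stage design
#'
#' Assembles the stage-1 critical value from \code{pi_markers}, the
#' Fisher-information weights from the stage sample sizes, and the joint
#' critical value from the marker-wise error budget.
#'
#' @param scenario A \code{\link{genetic_scenario}}.
#' @param cohort A \code{\link{cohort_spec}}.
#' @param allocation A \code{\link{stage_allocation}}.
#' @param step Integration step for the bisection integrand.
#' @return An object of class \code{joint_calibration}: list with \code{c1},
#'   \code{c_joint}, \code{w1}, \code{w2}, \code{info1}, \code{info2}.
#' @export
joint_calibration <- function(scenario, cohort, allocation, step = 0.005) {
  n <- stage_sizes(cohort, allocation)
  p_bar <- (cohort$n_cases * scenario$case_freq +
              cohort$n_controls * scenario$control_freq) /
    (cohort$n_cases + cohort$n_controls)
  w <- information_weights(p_bar, n$nA1, n$nU1, n$nA2, n$nU2)
  c1 <- stage1_critical(allocation$pi_markers)
  cj <- joint_critical(c1, w$w1, w$w2, cohort$alpha_marker, step = step)
  structure(list(c1 = c1, c_joint = cj, w1 = w$w1, w2 = w$w2,
                 info1 = w$info1, info2 = w$info2),
            class = "joint_calibration")
}

# Continuous (unrounded) stage-wise sample sizes implied by an allocation.
stage_sizes <- function(cohort, allocation) {
  list(nA1 = allocation$pi_cases * cohort$n_cases,
       nU1 = allocation$pi_controls * cohort$n_controls,
       nA2 = (1 - allocation$pi_cases) * cohort$n_cases,
       nU2 = (1 - allocation$pi_controls) * cohort$n_controls)
}

#' Evaluate one two-stage design
#'
#' Computes the stage-1 power, total (joint) power, expected genotyping cost
#' and the calibration of a single design. Stage sample sizes are the
#' continuous products \eqn{\pi \cdot n} (no rounding); Monte Carlo
#' verification rounds instead (see \code{\link{simulate_two_stage}}).
#'
#' @inheritParams joint_calibration
#' @return An object of class \code{design_evaluation}: list with
#'   \code{power_stage1}, \code{power_total}, \code{expected_cost},
#'   \code{calibration}, and the inputs \code{allocation}.
#' @examples
#' co <- cohort_spec(1000, 1, 3e5, 1, 10)
#' sc <- genetic_scenario(0.10, 0.10, 1.6)
#' evaluate_design(sc, co, stage_allocation(0.5, 0.5, 0.05))
#' @export
evaluate_design <- function(scenario, cohort, allocation, step = 0.005) {
  n <- stage_sizes(cohort, allocation)
  calib <- joint_calibration(scenario, cohort, allocation, step = step)
  m1 <- stage_statistic_moments(scenario$case_freq, scenario$control_freq,
                                n$nA1, n$nU1)
  p1 <- stage1_power(m1, calib$c1)
  if (calib$w2 > 0) {
    m2 <- stage_statistic_moments(scenario$case_freq, scenario$control_freq,
                                  n$nA2, n$nU2)
  } else {
    m2 <- structure(list(mean = 0, variance = 1), class = "stage_moments")
  }
  pt <- joint_power(m1, m2, calib, step = step)
  structure(
    list(power_stage1 = p1, power_total = min(pt, p1),
         expected_cost = expected_cost(cohort, allocation),
         calibration = calib, allocation = allocation),
    class = "design_evaluation")
}

#' @export
print.design_evaluation <- function(x, ...) {
  a <- x$allocation
  cat("Two-stage design evaluation\n")
  cat(sprintf("  allocation (pi_A, pi_U, pi_m) = (%g, %g, %g)\n",
              a$pi_cases, a$pi_controls, a$pi_markers))
  cat(sprintf("  critical values c1, cJ       = %.4f, %.4f\n",
              x$calibration$c1, x$calibration$c_joint))
  cat(sprintf("  weights w1, w2               = %.4f, %.4f\n",
              x$calibration$w1, x$calibration$w2))
  cat(sprintf("  stage-1 power                = %.4f\n", x$power_stage1))
  cat(sprintf("  total (joint) power          = %.4f\n", x$power_total))
  cat(sprintf("  expected cost                = %.4g\n", x$expected_cost))
  invisible(x)
}
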