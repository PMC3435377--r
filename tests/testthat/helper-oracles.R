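# Independent oracles used across the suite.

# Genotype-enumeration oracle for the multiplicative disease model: walks
# the three HWE genotypes with penetrances f0 * r^g and accumulates allele
# frequencies conditional on case/control status. Independent of the
# closed-form path in derive_case_control_freqs().
enum_case_control_freqs <- function(K, p, r) {
  g <- 0:2
  geno <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  f0 <- K / sum(geno * r^g)          # solves prevalence = E[penetrance]
  pen <- f0 * r^g
  stopifnot(all(pen <= 1 + 1e-12))
  prev <- sum(geno * pen)
  c(case_freq = sum((g / 2) * geno * pen) / prev,
    control_freq = sum((g / 2) * geno * (1 - pen)) / (1 - prev))
}

# Empirical z-statistics of the allele-frequency test over binomial draws.
mc_z_stats <- function(p_case, p_control, n_cases, n_controls, n_rep) {
  xA <- rbinom(n_rep, 2 * n_cases, p_case)
  xU <- rbinom(n_rep, 2 * n_controls, p_control)
  pA <- xA / (2 * n_cases); pU <- xU / (2 * n_controls)
  pbar <- (xA + xU) / (2 * (n_cases + n_controls))
  se <- sqrt(pbar * (1 - pbar) * (1 / (2 * n_cases) + 1 / (2 * n_controls)))
  z <- (pA - pU) / se
  z[!is.finite(z)] <- 0
  z
}

# Adaptive-quadrature oracle for the null double-rejection probability,
# independent of the package's midpoint cubature.
quad_double_rejection <- function(c1, cj, w1, w2) {
  f <- function(z1)
    dnorm(z1) * (pnorm((cj - w1 * z1) / w2, lower.tail = FALSE) +
                   pnorm((-cj - w1 * z1) / w2))
  stats::integrate(f, c1, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value +
    stats::integrate(f, -Inf, -c1, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Shrunken test fixtures: a small cohort with an elevated marker-wise error
# so Monte Carlo checks resolve at modest replicate counts.
small_cohort <- function(t = 2, alpha = 0.05, M = 1000)
  cohort_spec(n_cases = 500, control_ratio = t, n_markers = M,
              cost_stage1 = 1, cost_stage2 = 10, alpha_experiment = alpha)

focal_cohort <- function(t = 1, C2 = 10)
  cohort_spec(n_cases = 1000, control_ratio = t, n_markers = 3e5,
              cost_stage1 = 1, cost_stage2 = C2)
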