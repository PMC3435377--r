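#' Disease model scenario under Hardy-Weinberg equilibrium
#'
#' Builds a \code{genetic_scenario} describing a biallelic susceptibility
#' marker under the multiplicative model of genetic effects: genotype
#' penetrances are \eqn{f_g = f_0 r^g} for risk-allele count
#' \eqn{g \in \{0,1,2\}}, with the baseline penetrance \eqn{f_0} solved from
#' the disease prevalence \eqn{K = f_0 (1 - p + p r)^2}. Case and control
#' risk-allele frequencies follow in closed form (see
#' \code{\link{derive_case_control_freqs}}). Controls are unaffected
#' individuals, not population controls.
#'
#' @param prevalence Disease prevalence \eqn{K}, in (0, 1).
#' @param risk_allele_freq Population risk-allele frequency \eqn{p}, in (0, 1).
#' @param rel_risk Per-allele relative risk \eqn{r \ge 1}.
#'
#' @return An object of class \code{genetic_scenario}: a list with elements
#'   \code{prevalence}, \code{pop_freq}, \code{rel_risk}, \code{case_freq}
#'   (\eqn{p_A}) and \code{control_freq} (\eqn{p_U}).
#' @examples
#' genetic_scenario(prevalence = 0.10, risk_allele_freq = 0.10, rel_risk = 1.5)
#' @export
genetic_scenario <- function(prevalence, risk_allele_freq, rel_risk) {
  fr <- derive_case_control_freqs(prevalence, risk_allele_freq, rel_risk)
  structure(
    list(prevalence = prevalence, pop_freq = risk_allele_freq,
         rel_risk = rel_risk, case_freq = fr[["case_freq"]],
         control_freq = fr[["control_freq"]]),
    class = "genetic_scenario")
}

#' @export
print.genetic_scenario <- function(x, ...) {
  cat("Multiplicative disease model (HWE)\n")
  cat(sprintf("  prevalence K        = %.4g\n", x$prevalence))
  cat(sprintf("  risk allele freq p  = %.4g\n", x$pop_freq))
  cat(sprintf("  per-allele RR r     = %.6g\n", x$rel_risk))
  cat(sprintf("  case freq p_A       = %.6g\n", x$case_freq))
  cat(sprintf("  control freq p_U    = %.6g\n", x$control_freq))
  invisible(x)
}

#' Case and control risk-allele frequencies under the multiplicative model
#'
#' Under Hardy-Weinberg equilibrium with genotype penetrances
#' \eqn{f_g = f_0 r^g}, prevalence fixes \eqn{f_0 = K / (1 - p + p r)^2} and
#' the risk-allele frequency among cases is \eqn{p_A = p r / (1 - p + p r)}.
#' The control (unaffected) frequency follows from the law of total
#' probability, \eqn{p_U = (p - K p_A) / (1 - K)}.
#'
#' @param K Disease prevalence, in (0, 1).
#' @param p Population risk-allele frequency, in (0, 1).
#' @param r Per-allele relative risk, \eqn{r \ge 1}.
#'
#' @return Named numeric vector with elements \code{case_freq} and
#'   \code{control_freq}.
#' @export
derive_case_control_freqs <- function(K, p, r) {
  if (!is.finite(K) || K <= 0 || K >= 1)
    stop("prevalence K must lie in (0, 1)")
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("risk allele frequency p must lie in (0, 1)")
  if (!is.finite(r) || r < 1)
    stop("per-allele relative risk r must be >= 1")
  d <- 1 - p + p * r
  f0 <- K / d^2
  if (f0 * r^2 > 1 + 1e-12)
    stop("infeasible model: homozygote penetrance f0 * r^2 exceeds 1")
  p_A <- p * r / d
  p_U <- p * (1 - f0 * r * d) / (1 - K)
  c(case_freq = p_A, control_freq = p_U)
}

# Largest per-allele relative risk keeping the homozygote penetrance <= 1.
max_feasible_rel_risk <- function(K, p) {
  s <- sqrt(K)
  if (s <= p) return(Inf)
  (1 - p) / (s - p)
}

#' Analytic power of a one-stage allele-frequency test
#'
#' Power of the two-sided z-test comparing case and control allele
#' frequencies on the full sample, standardized by the null pooled-variance
#' standard error (2n chromosomes per n diploid individuals).
#'
#' @param p_case,p_control Case and control risk-allele frequencies, in (0, 1).
#' @param n_cases,n_controls Numbers of case and control individuals.
#' @param alpha_marker Marker-wise two-sided type-I error rate.
#'
#' @return Power, a probability. Equals \code{alpha_marker} when
#'   \code{p_case == p_control}.
#' @export
one_stage_power <- function(p_case, p_control, n_cases, n_controls,
                            alpha_marker) {
  stopifnot(p_case > 0, p_case < 1, p_control > 0, p_control < 1,
            n_cases >= 1, n_controls >= 1,
            alpha_marker > 0, alpha_marker < 1)
  m <- stage_statistic_moments(p_case, p_control, n_cases, n_controls)
  cv <- stats::qnorm(1 - alpha_marker / 2)
  stage1_power(m, cv)
}

#' Calibrate the per-allele relative risk to a target one-stage power
#'
#' Finds, by bisection on \eqn{r}, the multiplicative-model scenario whose
#' full-sample two-sided allele-frequency test attains \code{target_power}
#' at the cohort's marker-wise (Bonferroni) error rate. Power is continuous
#' and strictly increasing in \eqn{r}, so the root is unique.
#'
#' @param K Disease prevalence.
#' @param p Population risk-allele frequency.
#' @param cohort A \code{\link{cohort_spec}}.
#' @param target_power Desired one-stage power, in
#'   (\code{alpha_marker}, 1).
#' @param tol Absolute power tolerance of the root search.
#'
#' @return A \code{\link{genetic_scenario}} whose recomputed one-stage power
#'   is \code{target_power} to within \code{tol}.
#' @examples
#' co <- cohort_spec(n_cases = 1000, control_ratio = 1, n_markers = 3e5,
#'                   cost_stage1 = 1, cost_stage2 = 10)
#' sc <- calibrate_rel_risk(K = 0.10, p = 0.10, cohort = co,
#'                          target_power = 0.80)
#' @export
calibrate_rel_risk <- function(K, p, cohort, target_power, tol = 1e-8) {
  stopifnot(inherits(cohort, "cohort_spec"))
  aM <- cohort$alpha_marker
  if (target_power <= aM || target_power >= 1)
    stop("target_power must lie in (alpha_marker, 1)")
  nA <- cohort$n_cases
  nU <- cohort$control_ratio * cohort$n_cases
  pw <- function(r) {
    fr <- derive_case_control_freqs(K, p, r)
    one_stage_power(fr[[1]], fr[[2]], nA, nU, aM)
  }
  r_hi <- min(50, max_feasible_rel_risk(K, p) - 1e-9)
  if (pw(r_hi) < target_power)
    stop("calibration infeasible: target power not attainable for any ",
         "feasible relative risk")
  lo <- 1; hi <- r_hi
  repeat {
    mid <- (lo + hi) / 2
    f <- pw(mid) - target_power
    if (abs(f) < tol || (hi - lo) < 1e-13) break
    if (f > 0) hi <- mid else lo <- mid
  }
  genetic_scenario(K, p, mid)
}
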