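#' Cohort and genotyping-cost specification
#'
#' Describes the study resources a two-stage GWAS design allocates: the case
#' and control sample sizes, the number of markers on the stage-1 (whole
#' genome) platform, per-genotype costs for each stage, and the error-rate
#' budget. The marker-wise type-I error is the experiment-wise rate divided
#' by the number of markers (Bonferroni).
#'
#' @param n_cases Total number of cases \eqn{N}.
#' @param control_ratio Ratio \eqn{t} of controls to cases
#'   (\code{n_controls = t * n_cases}).
#' @param n_markers Number of biallelic markers \eqn{M} genotyped in stage 1.
#' @param cost_stage1,cost_stage2 Per-genotype costs \eqn{C_1}, \eqn{C_2}.
#'   The conventional unit is \eqn{C_1 = 1}.
#' @param alpha_experiment Experiment-wise two-sided type-I error rate.
#'
#' @return An object of class \code{cohort_spec}, a list with the above
#'   fields plus \code{n_controls} and \code{alpha_marker}.
#' @examples
#' cohort_spec(n_cases = 1000, control_ratio = 8, n_markers = 300000,
#'             cost_stage1 = 1, cost_stage2 = 10)
#' @export
cohort_spec <- function(n_cases, control_ratio = 1, n_markers,
                        cost_stage1 = 1, cost_stage2,
                        alpha_experiment = 0.05) {
  stopifnot(n_cases >= 1, control_ratio >= 1, n_markers >= 1,
            cost_stage1 > 0, cost_stage2 > 0,
            alpha_experiment > 0, alpha_experiment < 1)
  structure(
    list(n_cases = n_cases, control_ratio = control_ratio,
         n_controls = control_ratio * n_cases, n_markers = n_markers,
         cost_stage1 = cost_stage1, cost_stage2 = cost_stage2,
         alpha_experiment = alpha_experiment,
         alpha_marker = alpha_experiment / n_markers),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Two-stage GWAS cohort\n")
  cat(sprintf("  cases N              = %g\n", x$n_cases))
  cat(sprintf("  controls t*N         = %g (t = %g)\n",
              x$n_controls, x$control_ratio))
  cat(sprintf("  markers M            = %g\n", x$n_markers))
  cat(sprintf("  costs C1, C2         = %g, %g per genotype\n",
              x$cost_stage1, x$cost_stage2))
  cat(sprintf("  alpha (experiment)   = %g\n", x$alpha_experiment))
  cat(sprintf("  alpha (marker-wise)  = %.4g\n", x$alpha_marker))
  invisible(x)
}

#' Stage allocation of a two-stage design
#'
#' The design triple: proportions of cases and controls genotyped in stage 1
#' and the expected proportion of markers passed to stage 2 under the null.
#' \code{pi_markers} is not the type-I error rate; it sets the stage-1
#' critical value, and so governs cost, while the joint critical value
#' controls the error rate.
#'
#' @param pi_cases Proportion \eqn{\pi_A} of cases allocated to stage 1,
#'   in (0, 1].
#' @param pi_controls Proportion \eqn{\pi_U} of controls allocated to
#'   stage 1, in (0, 1].
#' @param pi_markers Expected null proportion \eqn{\pi_{markers}} of markers
#'   followed up in stage 2, in (0, 1].
#'
#' @return An object of class \code{stage_allocation}.
#' @export
stage_allocation <- function(pi_cases, pi_controls, pi_markers) {
  stopifnot(pi_cases > 0, pi_cases <= 1, pi_controls > 0, pi_controls <= 1,
            pi_markers > 0, pi_markers <= 1)
  structure(list(pi_cases = unname(pi_cases),
                 pi_controls = unname(pi_controls),
                 pi_markers = unname(pi_markers)),
            class = "stage_allocation")
}

#' @export
print.stage_allocation <- function(x, ...) {
  cat(sprintf(
    "Stage allocation: pi_cases = %g, pi_controls = %g, pi_markers = %g\n",
    x$pi_cases, x$pi_controls, x$pi_markers))
  invisible(x)
}
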