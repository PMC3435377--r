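#' Monte Carlo verification of a two-stage design
#'
#' Replays the full two-stage decision on synthetic allele-count data drawn
#' under the calibrated disease model. Each replicate draws stage-1 case and
#' control risk-allele counts \eqn{X \sim Binomial(2n, p)} (diploid
#' individuals; stage sizes are \eqn{\pi n} rounded to the nearest integer),
#' computes the plug-in stage-1 z-statistic (estimated frequencies, pooled
#' standard error), and passes iff \eqn{|Z_1| > c_1}. Passing replicates
#' draw stage-2 counts — optionally at batch-shifted frequencies
#' \code{batch_scale * p} — and reject iff
#' \eqn{|w_1 Z_1 + w_2 Z_2| > c_J}. Only the susceptibility marker is
#' simulated: power is marker-wise, and the \eqn{M} markers enter the design
#' only through the error budget and the cost.
#'
#' A replicate whose estimated pooled frequency is 0 or 1 has its statistic
#' set to 0 (non-rejection) and is still counted.
#'
#' @param scenario A \code{\link{genetic_scenario}}.
#' @param cohort A \code{\link{cohort_spec}}.
#' @param allocation A \code{\link{stage_allocation}}.
#' @param calibration A \code{\link{joint_calibration}} for this design; if
#'   \code{NULL} it is computed.
#' @param n_replicates Number of simulated replicates.
#' @param seed Integer RNG seed; identical seeds give identical estimates.
#' @param batch_scale Multiplier applied to both stage-2 case and control
#'   frequencies (1 = no batch effect), results clipped to (0, 1).
#'
#' @return An object of class \code{twostage_sim}: list with
#'   \code{rejection_rate} (empirical total power), \code{stage1_rate},
#'   \code{n_replicates}, \code{standard_error}, \code{seed},
#'   \code{batch_scale}.
#' @examples
#' co <- cohort_spec(1000, 1, 3e5, 1, 10)
#' sc <- genetic_scenario(0.10, 0.10, 1.6)
#' al <- stage_allocation(0.5, 0.5, 0.05)
#' simulate_two_stage(sc, co, al, n_replicates = 1000, seed = 1)
#' @export
simulate_two_stage <- function(scenario, cohort, allocation,
                               calibration = NULL, n_replicates = 10000,
                               seed = NULL, batch_scale = 1) {
  stopifnot(batch_scale > 0,
            batch_scale * scenario$case_freq < 1,
            batch_scale * scenario$control_freq < 1)
  if (is.null(calibration))
    calibration <- joint_calibration(scenario, cohort, allocation)
  if (!is.null(seed)) set.seed(seed)
  nA1 <- round(allocation$pi_cases * cohort$n_cases)
  nU1 <- round(allocation$pi_controls * cohort$n_controls)
  nA2 <- round((1 - allocation$pi_cases) * cohort$n_cases)
  nU2 <- round((1 - allocation$pi_controls) * cohort$n_controls)
  if (nA1 < 1 || nU1 < 1)
    stop("degenerate stage 1: no sampled chromosomes")
  two_sided_z <- function(xA, xU, nA, nU) {
    pA <- xA / (2 * nA); pU <- xU / (2 * nU)
    pbar <- (xA + xU) / (2 * nA + 2 * nU)
    se <- sqrt(pbar * (1 - pbar) * (1 / (2 * nA) + 1 / (2 * nU)))
    z <- (pA - pU) / se
    z[!is.finite(z)] <- 0  # monomorphic replicate: forced non-rejection
    z
  }
  pA <- scenario$case_freq; pU <- scenario$control_freq
  z1 <- two_sided_z(stats::rbinom(n_replicates, 2 * nA1, pA),
                    stats::rbinom(n_replicates, 2 * nU1, pU), nA1, nU1)
  pass <- abs(z1) > calibration$c1
  if (calibration$w2 > 0 && any(pass)) {
    if (nA2 < 1 || nU2 < 1)
      stop("degenerate stage 2: nonzero weight but no sampled chromosomes")
    np <- sum(pass)
    pA2 <- min(max(batch_scale * pA, 1e-9), 1 - 1e-9)
    pU2 <- min(max(batch_scale * pU, 1e-9), 1 - 1e-9)
    z2 <- two_sided_z(stats::rbinom(np, 2 * nA2, pA2),
                      stats::rbinom(np, 2 * nU2, pU2), nA2, nU2)
    zj <- calibration$w1 * z1[pass] + calibration$w2 * z2
    reject <- pass
    reject[pass] <- abs(zj) > calibration$c_joint
  } else {
    reject <- pass & (abs(calibration$w1 * z1) > calibration$c_joint)
  }
  rate <- mean(reject)
  structure(
    list(rejection_rate = rate, stage1_rate = mean(pass),
         n_replicates = n_replicates,
         standard_error = sqrt(rate * (1 - rate) / n_replicates),
         seed = seed, batch_scale = batch_scale),
    class = "twostage_sim")
}

#' @export
print.twostage_sim <- function(x, ...) {
  cat("Two-stage Monte Carlo verification\n")
  cat(sprintf("  replicates    = %d (seed %s, batch scale %g)\n",
              x$n_replicates,
              if (is.null(x$seed)) "none" else format(x$seed),
              x$batch_scale))
  cat(sprintf("  stage-1 rate  = %.4f\n", x$stage1_rate))
  cat(sprintf("  power (both)  = %.4f (SE %.4f)\n",
              x$rejection_rate, x$standard_error))
  invisible(x)
}

#' Batch-effect sensitivity of a design
#'
#' Re-runs the Monte Carlo verification with the stage-2 case and control
#' frequencies scaled to 90\%, 100\% and 110\% of those used to calibrate
#' the design, each run re-seeded with the same base seed.
#'
#' @inheritParams simulate_two_stage
#' @param scales Batch scale factors to evaluate.
#' @return A data frame with one row per scale: \code{batch_scale},
#'   \code{rejection_rate}, \code{stage1_rate}, \code{standard_error},
#'   \code{n_replicates}, \code{seed}.
#' @export
batch_sensitivity <- function(scenario, cohort, allocation,
                              calibration = NULL, n_replicates = 10000,
                              seed = NULL, scales = c(0.9, 1.0, 1.1)) {
  if (is.null(calibration))
    calibration <- joint_calibration(scenario, cohort, allocation)
  rows <- lapply(scales, function(s) {
    est <- simulate_two_stage(scenario, cohort, allocation, calibration,
                              n_replicates = n_replicates, seed = seed,
                              batch_scale = s)
    data.frame(batch_scale = s, rejection_rate = est$rejection_rate,
               stage1_rate = est$stage1_rate,
               standard_error = est$standard_error,
               n_replicates = n_replicates,
               seed = if (is.null(seed)) NA_integer_ else seed)
  })
  do.call(rbind, rows)
}

#' Monte Carlo verification of a fitted design
#'
#' \code{simulate} method for \code{\link{twostage_design}} objects: runs
#' \code{\link{simulate_two_stage}} on the fitted allocation and
#' calibration.
#'
#' @param object A feasible \code{twostage_design}.
#' @param nsim Number of replicates.
#' @param seed Integer RNG seed.
#' @param batch_scale Stage-2 frequency multiplier.
#' @param ... Unused.
#' @return A \code{twostage_sim} object.
#' @export
simulate.twostage_design <- function(object, nsim = 10000, seed = NULL,
                                     batch_scale = 1, ...) {
  if (!object$feasible) stop("cannot simulate an infeasible design")
  simulate_two_stage(object$scenario, object$cohort, object$allocation,
                     object$evaluation$calibration, n_replicates = nsim,
                     seed = seed, batch_scale = batch_scale)
}
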