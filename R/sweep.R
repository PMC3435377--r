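#' Sweep of optimal designs over experimental conditions
#'
#' For each condition (one row of \code{conditions}), calibrates the disease
#' model to the one-stage power baseline, computes the unrestricted and the
#' equality-restricted minimum-cost designs at the two-stage power target,
#' compares their costs with each other and with the one-stage design, and
#' optionally verifies the unrestricted design by Monte Carlo. One output
#' row per condition; every input needed to re-run the condition is echoed
#' into the row.
#'
#' @param conditions Data frame with columns \code{K} (prevalence), \code{p}
#'   (risk-allele frequency), \code{t} (control:case ratio) and \code{C2}
#'   (stage-2 per-genotype cost). Missing columns fall back to the defaults.
#' @param n_cases,n_markers,cost_stage1,alpha_experiment Cohort constants
#'   shared across conditions.
#' @param one_stage_target One-stage calibration power baseline.
#' @param target_power Two-stage design power target.
#' @param grid A \code{\link{grid_spec}}.
#' @param search Search strategy, see \code{\link{twostage_design}}.
#' @param n_replicates Monte Carlo replicates per condition; 0 disables
#'   verification.
#' @param seed Base RNG seed; condition \code{i} uses \code{seed + i - 1}.
#' @param verbose Print a line per condition.
#'
#' @return A data frame of class \code{twostage_sweep} with one row per
#'   condition: inputs, calibrated \code{r}, \code{p_case}/\code{p_control},
#'   optimal allocation, critical values, powers, costs, and relative cost
#'   advantages versus the one-stage and the equality-restricted designs
#'   (plus Monte Carlo columns when requested). Infeasible conditions are
#'   flagged with \code{feasible = FALSE} and NA results.
#' @examples
#' \donttest{
#' run_sweep(data.frame(K = 0.1, p = 0.1, t = 1, C2 = 10),
#'           grid = grid_spec(0.1, 0.01, 0.2), n_replicates = 0)
#' }
#' @export
run_sweep <- function(conditions,
                      n_cases = 1000, n_markers = 300000, cost_stage1 = 1,
                      alpha_experiment = 0.05, one_stage_target = 0.80,
                      target_power = 0.78, grid = grid_spec(),
                      search = "coarse_to_fine", n_replicates = 0,
                      seed = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(conditions))
  defaults <- list(K = 0.10, p = 0.10, t = 1, C2 = 10)
  for (nm in names(defaults))
    if (is.null(conditions[[nm]])) conditions[[nm]] <- defaults[[nm]]
  rows <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    cd <- conditions[i, ]
    row <- sweep_condition(cd$K, cd$p, cd$t, cd$C2,
                           n_cases = n_cases, n_markers = n_markers,
                           cost_stage1 = cost_stage1,
                           alpha_experiment = alpha_experiment,
                           one_stage_target = one_stage_target,
                           target_power = target_power, grid = grid,
                           search = search, n_replicates = n_replicates,
                           seed = if (is.null(seed)) NULL else seed + i - 1)
    rows[[i]] <- row
    if (verbose)
      message(sprintf(
        "condition %d/%d (K=%g p=%g t=%g C2=%g): %s", i, nrow(conditions),
        cd$K, cd$p, cd$t, cd$C2,
        if (row$feasible) sprintf("pi=(%.2f, %.2f, %.4f) cost %.4g",
                                  row$pi_cases, row$pi_controls,
                                  row$pi_markers, row$cost)
        else "infeasible"))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  class(out) <- c("twostage_sweep", class(out))
  out
}

sweep_condition <- function(K, p, t, C2, n_cases, n_markers, cost_stage1,
                            alpha_experiment, one_stage_target,
                            target_power, grid, search, n_replicates,
                            seed) {
  cohort <- cohort_spec(n_cases, t, n_markers, cost_stage1, C2,
                        alpha_experiment)
  base <- data.frame(K = K, p = p, t = t, C2 = C2, n_cases = n_cases,
                     n_markers = n_markers, C1 = cost_stage1,
                     alpha_experiment = alpha_experiment,
                     one_stage_target = one_stage_target,
                     target_power = target_power)
  na_row <- function(msg) {
    cbind(base, data.frame(
      feasible = FALSE, note = msg, r = NA, p_case = NA, p_control = NA,
      pi_cases = NA, pi_controls = NA, pi_markers = NA, c1 = NA,
      c_joint = NA, power_stage1 = NA, power_total = NA, cost = NA,
      cost_one_stage = NA, cost_restricted = NA,
      advantage_vs_one_stage = NA, advantage_vs_restricted = NA))
  }
  scenario <- tryCatch(
    calibrate_rel_risk(K, p, cohort, one_stage_target),
    error = function(e) NULL)
  if (is.null(scenario)) return(na_row("calibration infeasible"))
  un <- min_cost_design(scenario, cohort, target_power, grid = grid,
                        search = search)
  if (!un$feasible) return(na_row("no feasible design on grid"))
  re <- equality_restricted_min_cost(scenario, cohort, target_power,
                                     grid = grid)
  one <- one_stage_design(scenario, cohort)
  ev <- un$evaluation
  out <- cbind(base, data.frame(
    feasible = TRUE, note = "", r = scenario$rel_risk,
    p_case = scenario$case_freq, p_control = scenario$control_freq,
    pi_cases = un$allocation$pi_cases,
    pi_controls = un$allocation$pi_controls,
    pi_markers = un$allocation$pi_markers,
    c1 = ev$calibration$c1, c_joint = ev$calibration$c_joint,
    power_stage1 = ev$power_stage1, power_total = ev$power_total,
    cost = ev$expected_cost, cost_one_stage = one$expected_cost,
    cost_restricted = if (re$feasible) re$evaluation$expected_cost else NA,
    advantage_vs_one_stage = cost_advantage(one, un),
    advantage_vs_restricted = if (re$feasible) cost_advantage(re, un)
                              else NA))
  if (n_replicates > 0) {
    est <- simulate_two_stage(scenario, cohort, un$allocation,
                              ev$calibration, n_replicates = n_replicates,
                              seed = seed)
    out$power_mc <- est$rejection_rate
    out$power_mc_se <- est$standard_error
    out$mc_replicates <- n_replicates
    out$mc_seed <- if (is.null(seed)) NA_integer_ else seed
  }
  out
}
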