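#' Expected genotyping cost of a two-stage design
#'
#' \deqn{C_1 M (\pi_A N + \pi_U t N) +
#'       C_2 \pi_{m} M ((1-\pi_A) N + (1-\pi_U) t N)}
#' Stage-2 cost is an expectation: under the null a proportion
#' \eqn{\pi_{markers}} of the \eqn{M} markers is followed up.
#'
#' @param cohort A \code{\link{cohort_spec}}.
#' @param allocation A \code{\link{stage_allocation}} (or list with the same
#'   fields).
#' @return Cost in units of the stage-1 per-genotype cost.
#' @export
expected_cost <- function(cohort, allocation) {
  N <- cohort$n_cases; tN <- cohort$n_controls; M <- cohort$n_markers
  cohort$cost_stage1 * M *
    (allocation$pi_cases * N + allocation$pi_controls * tN) +
    cohort$cost_stage2 * allocation$pi_markers * M *
      ((1 - allocation$pi_cases) * N + (1 - allocation$pi_controls) * tN)
}

# Grid of allocation proportions: step, 2*step, ..., 1. Zero is excluded
# because stage 1 genotypes every marker and needs both cases and controls.
alloc_grid <- function(step) seq(step, 1, by = step)

# pi_markers grid: from max(10 * alpha_marker, step) up to 1, floored to the
# step so joint_critical stays feasible (stage-1 pass rate above the budget).
marker_grid <- function(step, alpha_marker) {
  lo <- max(ceiling(10 * alpha_marker / step) * step, step)
  seq(lo, 1, by = step)
}

#' Grid-resolution specification for the design search
#'
#' @param step_alloc Step for the case/control stage-1 proportions
#'   (default 1\%, the reporting resolution).
#' @param step_markers Step for the marker pass proportion (default 0.1\%).
#' @param coarse_alloc Coarse-pass step for the allocation proportions used
#'   by the coarse-to-fine strategy.
#' @param n_refine Number of best coarse candidates around which the fine
#'   pass searches (each within one coarse step).
#' @return A list of class \code{grid_spec}.
#' @export
grid_spec <- function(step_alloc = 0.01, step_markers = 0.001,
                      coarse_alloc = 0.05, n_refine = 3) {
  stopifnot(step_alloc > 0, step_markers > 0)
  coarse_alloc <- max(coarse_alloc, step_alloc)
  structure(list(step_alloc = step_alloc, step_markers = step_markers,
                 coarse_alloc = coarse_alloc, n_refine = n_refine),
            class = "grid_spec")
}

# For a fixed (pi_A, pi_U) pair, find the smallest pi_markers on the grid
# whose total power reaches the target. Total power is nondecreasing in
# pi_markers (the stage-1 filter only removes rejections), so binary search
# over the grid applies. Returns NULL when even pi_markers = 1 falls short.
min_feasible_pi_m <- function(scenario, cohort, piA, piU, pm_grid,
                              target_power, step) {
  ev <- function(pm)
    evaluate_design(scenario, cohort, stage_allocation(piA, piU, pm),
                    step = step)
  n <- length(pm_grid)
  top <- ev(pm_grid[n])
  if (top$power_total < target_power) return(NULL)
  lo <- 1L; hi <- n; best <- top
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    e <- ev(pm_grid[mid])
    if (e$power_total >= target_power) {
      hi <- mid; best <- e
    } else lo <- mid + 1L
  }
  best
}

# Better-candidate predicate for min-cost search with the declared
# tie-break order: cost, then higher power, then smaller pi_markers, then
# smaller pi_cases.
cheaper_than <- function(cand, incumbent) {
  if (is.null(incumbent)) return(TRUE)
  eps <- 1e-9
  if (cand$expected_cost < incumbent$expected_cost - eps) return(TRUE)
  if (cand$expected_cost > incumbent$expected_cost + eps) return(FALSE)
  if (cand$power_total > incumbent$power_total + 1e-12) return(TRUE)
  if (cand$power_total < incumbent$power_total - 1e-12) return(FALSE)
  if (cand$allocation$pi_markers < incumbent$allocation$pi_markers - eps)
    return(TRUE)
  if (cand$allocation$pi_markers > incumbent$allocation$pi_markers + eps)
    return(FALSE)
  cand$allocation$pi_cases < incumbent$allocation$pi_cases - eps
}

# Scan a set of (pi_A, pi_U) pairs for the cheapest design meeting the
# power target; each pair contributes its minimal feasible pi_markers.
scan_min_cost <- function(scenario, cohort, pairs, pm_grid, target_power,
                          step) {
  best <- NULL
  per_pair <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    e <- min_feasible_pi_m(scenario, cohort, pairs[i, 1], pairs[i, 2],
                           pm_grid, target_power, step)
    per_pair[[i]] <- e
    if (!is.null(e) && cheaper_than(e, best)) best <- e
  }
  list(best = best, per_pair = per_pair)
}

refine_pairs <- function(scored, pairs, grid) {
  costs <- vapply(scored, function(e)
    if (is.null(e)) Inf else e$expected_cost, numeric(1))
  ord <- order(costs)[seq_len(min(grid$n_refine, sum(is.finite(costs))))]
  fine <- alloc_grid(grid$step_alloc)
  out <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    pa <- pairs[i, 1]; pu <- pairs[i, 2]
    a <- fine[abs(fine - pa) <= grid$coarse_alloc + 1e-12]
    u <- fine[abs(fine - pu) <= grid$coarse_alloc + 1e-12]
    out <- rbind(out, unname(as.matrix(expand.grid(a, u))))
  }
  unique(out)
}

#' Fit an optimal two-stage GWAS design
#'
#' The main design optimizer. Searches the grid of stage allocations
#' \eqn{(\pi_A, \pi_U, \pi_{markers})} for either the minimum-expected-cost
#' design subject to a total-power constraint (\code{objective =
#' "min_cost"}) or the maximum-total-power design subject to a cost budget
#' (\code{objective = "max_power"}). The default strategy is a coarse pass
#' over the allocation proportions followed by fine refinement (at 1\%
#' allocation and 0.1\% marker-proportion resolution) in the neighborhood of
#' the best coarse candidates; \code{search = "exhaustive"} scans the full
#' fine grid. For each allocation pair the marker proportion is resolved
#' directly: by binary search for the smallest feasible value (min-cost;
#' power is nondecreasing in \eqn{\pi_{markers}}) or as the largest
#' affordable grid value (max-power; cost is increasing in
#' \eqn{\pi_{markers}}).
#'
#' @param scenario A \code{\link{genetic_scenario}} (e.g. from
#'   \code{\link{calibrate_rel_risk}}).
#' @param cohort A \code{\link{cohort_spec}}.
#' @param objective \code{"min_cost"} or \code{"max_power"}.
#' @param target_power Required total power (min-cost mode).
#' @param cost_budget Maximum expected cost (max-power mode).
#' @param equal_allocation Force \eqn{\pi_A = \pi_U} (the equality-restricted
#'   baseline used by earlier two-stage design software).
#' @param grid A \code{\link{grid_spec}}.
#' @param search \code{"coarse_to_fine"} (default) or \code{"exhaustive"}.
#' @param step Integration step for the power computations.
#'
#' @return An object of class \code{twostage_design}: list with
#'   \code{allocation}, \code{evaluation} (a \code{design_evaluation}),
#'   \code{objective}, \code{constraint}, \code{feasible}, \code{grid},
#'   \code{scenario}, \code{cohort}.
#' @seealso \code{\link{min_cost_design}}, \code{\link{max_power_design}},
#'   \code{\link{simulate.twostage_design}}
#' @examples
#' \donttest{
#' co <- cohort_spec(1000, 1, 3e5, 1, 10)
#' sc <- calibrate_rel_risk(0.10, 0.10, co, target_power = 0.80)
#' d <- twostage_design(sc, co, target_power = 0.78,
#'                      grid = grid_spec(0.05, 0.005, 0.1))
#' print(d)
#' }
#' @export
twostage_design <- function(scenario, cohort,
                            objective = c("min_cost", "max_power"),
                            target_power = NULL, cost_budget = NULL,
                            equal_allocation = FALSE, grid = grid_spec(),
                            search = c("coarse_to_fine", "exhaustive"),
                            step = 0.005) {
  objective <- match.arg(objective)
  search <- match.arg(search)
  stopifnot(inherits(scenario, "genetic_scenario"),
            inherits(cohort, "cohort_spec"))
  if (objective == "min_cost" && is.null(target_power))
    stop("min_cost mode requires target_power")
  if (objective == "max_power" && is.null(cost_budget))
    stop("max_power mode requires cost_budget")

  pm_grid <- marker_grid(grid$step_markers, cohort$alpha_marker)
  fine <- alloc_grid(grid$step_alloc)
  pair_mat <- function(vals) {
    if (equal_allocation) unname(cbind(vals, vals))
    else unname(as.matrix(expand.grid(vals, vals)))
  }

  if (objective == "min_cost") {
    scan <- function(pairs)
      scan_min_cost(scenario, cohort, pairs, pm_grid, target_power, step)
    if (search == "exhaustive" || equal_allocation) {
      res <- scan(pair_mat(fine))
      best <- res$best
    } else {
      coarse_pairs <- pair_mat(alloc_grid(grid$coarse_alloc))
      coarse <- scan(coarse_pairs)
      best <- coarse$best
      if (!is.null(best)) {
        fine_pairs <- refine_pairs(coarse$per_pair, coarse_pairs, grid)
        ref <- scan(fine_pairs)
        if (!is.null(ref$best) && cheaper_than(ref$best, best))
          best <- ref$best
      }
    }
    constraint <- c(target_power = target_power)
  } else {
    scan <- function(pairs)
      scan_max_power(scenario, cohort, pairs, pm_grid, cost_budget, step)
    if (search == "exhaustive" || equal_allocation) {
      res <- scan(pair_mat(fine))
      best <- res$best
    } else {
      coarse_pairs <- pair_mat(alloc_grid(grid$coarse_alloc))
      coarse <- scan(coarse_pairs)
      best <- coarse$best
      if (!is.null(best)) {
        fine_pairs <- refine_pairs_power(coarse$per_pair, coarse_pairs, grid)
        ref <- scan(fine_pairs)
        if (!is.null(ref$best) && more_powerful_than(ref$best, best))
          best <- ref$best
      }
    }
    constraint <- c(cost_budget = cost_budget)
  }

  structure(
    list(allocation = if (is.null(best)) NULL else best$allocation,
         evaluation = best, objective = objective, constraint = constraint,
         feasible = !is.null(best), equal_allocation = equal_allocation,
         grid = grid, search = search, scenario = scenario, cohort = cohort),
    class = "twostage_design")
}

# Max-power counterparts ------------------------------------------------

more_powerful_than <- function(cand, incumbent) {
  if (is.null(incumbent)) return(TRUE)
  if (cand$power_total > incumbent$power_total + 1e-12) return(TRUE)
  if (cand$power_total < incumbent$power_total - 1e-12) return(FALSE)
  cand$expected_cost < incumbent$expected_cost - 1e-9
}

# For fixed (pi_A, pi_U): cost rises and power does not fall in pi_markers,
# so the best affordable design uses the largest pi_markers within budget
# (floored to the grid). One-stage pairs (both proportions 1) incur no
# stage-2 cost; they are evaluated at the grid floor.
scan_max_power <- function(scenario, cohort, pairs, pm_grid, budget, step) {
  N <- cohort$n_cases; tN <- cohort$n_controls; M <- cohort$n_markers
  best <- NULL
  per_pair <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    piA <- pairs[i, 1]; piU <- pairs[i, 2]
    cost1 <- cohort$cost_stage1 * M * (piA * N + piU * tN)
    n2 <- (1 - piA) * N + (1 - piU) * tN
    if (n2 <= 0) {
      if (cost1 > budget + 1e-9) next
      pm <- pm_grid[1]
    } else {
      pm_max <- (budget - cost1) / (cohort$cost_stage2 * M * n2)
      pm <- pm_grid[pm_grid <= pm_max + 1e-12]
      if (length(pm) == 0) next
      pm <- pm[length(pm)]
    }
    e <- evaluate_design(scenario, cohort, stage_allocation(piA, piU, pm),
                         step = step)
    if (e$expected_cost > budget + 1e-6) next
    per_pair[[i]] <- e
    if (more_powerful_than(e, best)) best <- e
  }
  list(best = best, per_pair = per_pair)
}

refine_pairs_power <- function(scored, pairs, grid) {
  pw <- vapply(scored, function(e)
    if (is.null(e)) -Inf else e$power_total, numeric(1))
  ord <- order(-pw)[seq_len(min(grid$n_refine, sum(is.finite(pw))))]
  fine <- alloc_grid(grid$step_alloc)
  out <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    pa <- pairs[i, 1]; pu <- pairs[i, 2]
    a <- fine[abs(fine - pa) <= grid$coarse_alloc + 1e-12]
    u <- fine[abs(fine - pu) <= grid$coarse_alloc + 1e-12]
    out <- rbind(out, unname(as.matrix(expand.grid(a, u))))
  }
  unique(out)
}

# Convenience wrappers ---------------------------------------------------

#' Minimum-cost design at a power target
#'
#' Wrapper around \code{\link{twostage_design}} with
#' \code{objective = "min_cost"}.
#' @inheritParams twostage_design
#' @param ... Passed on to \code{\link{twostage_design}}.
#' @return A \code{twostage_design} object.
#' @export
min_cost_design <- function(scenario, cohort, target_power, ...)
  twostage_design(scenario, cohort, "min_cost",
                  target_power = target_power, ...)

#' Maximum-power design at a cost budget
#'
#' Wrapper around \code{\link{twostage_design}} with
#' \code{objective = "max_power"}.
#' @inheritParams twostage_design
#' @param ... Passed on to \code{\link{twostage_design}}.
#' @return A \code{twostage_design} object.
#' @export
max_power_design <- function(scenario, cohort, cost_budget, ...)
  twostage_design(scenario, cohort, "max_power",
                  cost_budget = cost_budget, ...)

#' Equality-restricted minimum-cost design
#'
#' The classical baseline in which the same proportion of cases and controls
#' is allocated to stage 1 (\eqn{\pi_A = \pi_U}); solved exhaustively on the
#' fine grid since the restricted search is one-dimensional in the
#' allocation.
#' @inheritParams twostage_design
#' @param ... Passed on to \code{\link{twostage_design}}.
#' @return A \code{twostage_design} object.
#' @export
equality_restricted_min_cost <- function(scenario, cohort, target_power, ...)
  twostage_design(scenario, cohort, "min_cost",
                  target_power = target_power, equal_allocation = TRUE, ...)

#' One-stage reference design
#'
#' Evaluates the design that genotypes every sample on the stage-1 platform
#' (\eqn{\pi_A = \pi_U = 1}); its cost \eqn{C_1 M N (1 + t)} and power are
#' the comparison baseline for two-stage designs.
#' @inheritParams twostage_design
#' @return A \code{design_evaluation}.
#' @export
one_stage_design <- function(scenario, cohort) {
  evaluate_design(scenario, cohort,
                  stage_allocation(1, 1, max(0.001,
                                             10 * cohort$alpha_marker)))
}

#' Relative cost advantage of one design over another
#'
#' \code{100 * (1 - cost(candidate) / cost(reference))}: the percentage by
#' which the candidate undercuts the reference.
#'
#' @param reference,candidate \code{twostage_design} or
#'   \code{design_evaluation} objects (or anything with an
#'   \code{expected_cost}).
#' @return A percentage.
#' @export
cost_advantage <- function(reference, candidate) {
  get_cost <- function(x) {
    if (inherits(x, "twostage_design")) {
      if (!x$feasible) stop("design is infeasible; no cost to compare")
      x$evaluation$expected_cost
    } else x$expected_cost
  }
  rc <- get_cost(reference)
  if (rc == 0) stop("reference cost is zero")
  100 * (1 - get_cost(candidate) / rc)
}

# S3 methods ------------------------------------------------------------

#' @export
print.twostage_design <- function(x, ...) {
  cat(sprintf("Two-stage GWAS design (%s%s, %s search)\n",
              x$objective,
              if (x$equal_allocation) ", equality-restricted" else "",
              x$search))
  cat(sprintf("  constraint: %s = %g\n",
              names(x$constraint), x$constraint))
  if (!x$feasible) {
    cat("  no feasible design on the search grid\n")
    return(invisible(x))
  }
  a <- x$allocation
  cat(sprintf("  pi_cases = %.3f, pi_controls = %.3f, pi_markers = %.4f\n",
              a$pi_cases, a$pi_controls, a$pi_markers))
  cat(sprintf("  total power   = %.4f   (stage 1: %.4f)\n",
              x$evaluation$power_total, x$evaluation$power_stage1))
  cat(sprintf("  expected cost = %.6g\n", x$evaluation$expected_cost))
  invisible(x)
}

#' @export
coef.twostage_design <- function(object, ...) {
  if (!object$feasible) return(c(pi_cases = NA_real_,
                                 pi_controls = NA_real_,
                                 pi_markers = NA_real_))
  a <- object$allocation
  c(pi_cases = a$pi_cases, pi_controls = a$pi_controls,
    pi_markers = a$pi_markers)
}

#' @export
summary.twostage_design <- function(object, ...) {
  one <- one_stage_design(object$scenario, object$cohort)
  out <- list(design = object, one_stage = one,
              advantage_vs_one_stage =
                if (object$feasible) cost_advantage(one, object) else NA_real_)
  class(out) <- "summary.twostage_design"
  out
}

#' @export
print.summary.twostage_design <- function(x, ...) {
  print(x$design)
  if (x$design$feasible) {
    cat(sprintf("  one-stage cost  = %.6g (power %.4f)\n",
                x$one_stage$expected_cost, x$one_stage$power_total))
    cat(sprintf("  cost advantage vs one-stage = %.1f%%\n",
                x$advantage_vs_one_stage))
  }
  invisible(x)
}

#' Power/cost profile of a fitted design along the marker pass proportion
#'
#' Plots total power (left axis) and expected cost relative to the one-stage
#' design (right axis) as functions of \eqn{\pi_{markers}}, holding the
#' fitted case/control allocation fixed. Visualizes the trade the optimizer
#' resolved: power saturates in \eqn{\pi_{markers}} while cost keeps rising.
#'
#' @param x A feasible \code{twostage_design}.
#' @param n_points Number of profile points.
#' @param ... Unused.
#' @return Invisibly, a data frame of the profiled points.
#' @export
plot.twostage_design <- function(x, n_points = 25, ...) {
  if (!x$feasible) stop("cannot profile an infeasible design")
  a <- x$allocation
  pm <- exp(seq(log(max(10 * x$cohort$alpha_marker, 1e-4)), log(1),
                length.out = n_points))
  ev <- lapply(pm, function(p)
    evaluate_design(x$scenario, x$cohort,
                    stage_allocation(a$pi_cases, a$pi_controls, p)))
  pw <- vapply(ev, `[[`, numeric(1), "power_total")
  cost <- vapply(ev, `[[`, numeric(1), "expected_cost")
  one <- one_stage_design(x$scenario, x$cohort)$expected_cost
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(pm, pw, type = "l", log = "x", col = "firebrick", lwd = 2,
                 xlab = expression(pi[markers]), ylab = "total power",
                 ylim = c(0, 1))
  graphics::abline(v = a$pi_markers, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(pm, cost / one, type = "l", log = "x", col = "steelblue",
                 lwd = 2, axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, max(cost / one)))
  graphics::axis(4)
  graphics::mtext("cost / one-stage cost", side = 4, line = 2.5)
  invisible(data.frame(pi_markers = pm, power_total = pw,
                       expected_cost = cost))
}
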