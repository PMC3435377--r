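---
title: "Designing two-stage GWAS with unequal case/control allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing two-stage GWAS with unequal case/control allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostageGWAS)
```

## The design problem

A two-stage genome-wide association study (2S-GWAS) genotypes all $M$
markers on a first-stage subsample using a whole-genome platform, and
follows up only the markers with strong stage-1 association signals on the
remaining samples with a (per-genotype more expensive) custom platform. The
final call combines both stages. The design question is how to split $N$
cases and $tN$ controls between the stages, and how aggressive the stage-1
filter should be, so that the study either costs as little as possible at a
required power or achieves as much power as possible within a budget.

A design is the triple $(\pi_A, \pi_U, \pi_{m})$: the proportions of cases
and controls genotyped in stage 1, and the expected proportion of markers
passed to stage 2 when nothing is associated. Most earlier treatments force
$\pi_A = \pi_U$. This package searches the unrestricted space; the
advantage of letting $\pi_A \neq \pi_U$ grows when controls outnumber cases
($t > 1$), because information per genotyping dollar then differs between
cases and controls.

## Disease model and effect-size calibration

The scenario is a biallelic susceptibility marker under Hardy-Weinberg
equilibrium with multiplicative penetrances $f_g = f_0 r^g$ for risk-allele
count $g \in \{0,1,2\}$. Prevalence fixes the baseline penetrance,
$K = f_0 (1-p+pr)^2$, and the case allele frequency is
$p_A = pr/(1-p+pr)$; the control (unaffected) frequency follows from
$K p_A + (1-K) p_U = p$. The model is infeasible when $f_0 r^2 > 1$, which
bounds the admissible $r$ (for $K = p = 0.1$ at about $4.16$); the
effect-size calibration brackets its root search accordingly.

Rather than asking the user for an effect size, the standard workflow
calibrates $r$ (by bisection, to $10^{-8}$ in power) so that a *one-stage*
scan of the full cohort would attain a stated baseline power — 80% at the
Bonferroni marker-wise level $\alpha/M$ in the reference study — and then
targets a slightly lower total power (78%) for the two-stage design, since
staging always costs a little power.

```{r}
cohort <- cohort_spec(n_cases = 1000, control_ratio = 1, n_markers = 3e5,
                      cost_stage1 = 1, cost_stage2 = 10,
                      alpha_experiment = 0.05)
scenario <- calibrate_rel_risk(K = 0.10, p = 0.10, cohort,
                               target_power = 0.80)
scenario
```

## Test statistics and the joint analysis

Each stage compares estimated case/control allele frequencies with a
z-statistic standardized by the null pooled-variance standard error
(per-stage sample sizes, $2n$ chromosomes per $n$ diploid individuals).
Under the null each stage statistic is standard normal; under the
alternative it is approximately normal with mean
$(p_A - p_U)/SE_0$ and a variance given by the ratio of the alternative to
the null variance of the frequency difference.

Stage 1 passes a marker iff $|Z_1| > c_1$ with
$c_1 = \Phi^{-1}(1 - \pi_m/2)$, so $\pi_m$ of null markers proceed —
$\pi_m$ is a *cost* knob, not an error rate. The final decision uses the
information-weighted joint statistic $Z_J = w_1 Z_1 + w_2 Z_2$ with
$w_k \propto \sqrt{I_k}$, where $I_k$ is the stage's null-model Fisher
information (reciprocal null variance of the allele-frequency difference),
normalized so $w_1^2 + w_2^2 = 1$. The joint critical value $c_J$ is tuned
so that the null probability of rejecting at *both* stages,
$P(|Z_1| > c_1,\ |Z_J| > c_J)$, equals the marker-wise error $\alpha/M$.

Numerics: the bivariate tail probability is computed by midpoint
("rectangular") cubature of the conditional normal tail over the stage-1
rejection region, truncated at eight standard deviations, with a default
step of 0.005 standard-normal units; the step is shrunk per panel so the
region boundary at $c_1$ is hit exactly. $c_J$ is found by bisection on
$[0, 10]$, terminating at an absolute probability residual below
$10^{-12}$ (or bracket width $10^{-10}$). At the default step the cubature
is accurate to about $10^{-7}$ absolute (it is $O(h^2)$; refining the step
to $2 \times 10^{-4}$ takes it below $10^{-9}$, which the tests verify
against adaptive quadrature). Total power applies the same integral under
the alternative moments.

Two conventions were genuinely open and are fixed as follows. First, the
pooled frequency entering the information weights is the whole-cohort
expectation $(N p_A + tN p_U)/(N + tN)$, identical across stages, so the
weights stay normalized and interpretable when $\pi_A \neq \pi_U$ (each
stage's *moments* still use its own sample sizes). Second, no
sign-consistency filter is imposed between $Z_1$ and $Z_J$ beyond the
joint statistic's own averaging; both tests are two-sided throughout.

## The optimizer

```{r, eval = FALSE}
design <- min_cost_design(scenario, cohort, target_power = 0.78)
```

Expected cost is
$C_1 M (\pi_A N + \pi_U t N) + C_2 \pi_m M \{(1-\pi_A)N + (1-\pi_U)tN\}$,
in units of the stage-1 per-genotype cost ($C_1 = 1$ by convention).

The search runs on a grid: 1% steps in $\pi_A, \pi_U$ (the reporting
resolution) and 0.1% steps in $\pi_m$, with $\pi_m$ floored at
$\max(10\,\alpha/M, 0.001)$ so the stage-1 pass rate stays above the error
budget. Two structural monotonicities collapse one dimension of the search:
total power is nondecreasing and cost strictly increasing in $\pi_m$, so
for a fixed allocation pair the cheapest feasible $\pi_m$ is found by
binary search (min-cost mode) and the best affordable $\pi_m$ in closed
form (max-power mode). Over the allocation pairs the default strategy is a
coarse 5% pass refined to 1% around the three best coarse candidates;
`search = "exhaustive"` disables this, and the tests confirm the two agree
on reduced grids. Ties are broken toward higher power, then smaller
$\pi_m$, then smaller $\pi_A$ (min-cost), or toward lower cost
(max-power); the tie-break order is this package's convention. The power
constraint is evaluated at full numerical precision, not on rounded
displays. Analytic evaluation uses continuous $\pi \cdot n$ without
rounding; at the default 1% resolution with $N = 1000$ the grid points are
integers anyway.

Infeasible constraints (a power target above the one-stage ceiling, a
budget below every grid point) return an object with `feasible = FALSE`
rather than an error, so sweeps can continue past impossible conditions.

## Monte Carlo verification and what it does (not) show

`simulate_two_stage()` replays the full decision on synthetic data: per
replicate, binomial allele counts at the model frequencies (stage sizes
rounded to integers), *plug-in* z-statistics with estimated pooled standard
errors, the stage-1 filter, then the joint decision. Only the
susceptibility marker is simulated — power is marker-wise and markers are
independent in this framework, so the other $M - 1$ markers enter only
through $\alpha/M$ and cost. Batch effects between stages are emulated by
scaling both stage-2 frequencies to 90% or 110% of the design values.

Because the simulation uses estimated variances while the analytic power
uses expected ones, their agreement (within three binomial standard errors
plus a 0.005 allowance at $n = 1000$) also checks the asymptotic
approximation, not merely the integration. What passing does *not* show:
robustness to linkage disequilibrium, population stratification,
genotyping error beyond the frequency-scaling batch effect, or small-sample
behavior — none of which the generator emulates.

Replicate counts: the reference analyses used $10^5$; this package
defaults to $10^4$ in examples and tests (binomial SE about 0.004 at 78%
power) and the verification scripts use $10^4$ per design. All simulation
entry points take an integer seed and are exactly reproducible from it.

## Problem sizes and runtimes

A full-resolution min-cost search at the reference conditions evaluates a
few thousand calibrated designs and takes tens of seconds; the bundled
sweeps (eight conditions, unrestricted plus equality-restricted searches)
run in a few minutes. Unit tests exercise the optimizer on reduced grids
(5-10% allocation, 0.5-1% marker steps) with exhaustive cross-checks, and
elevate the marker-wise error to $10^{-3}$ where a null rejection rate
must be measurable at feasible replicate counts.

## Known limitations

* Asymptotic normal approximations throughout; no exact small-sample or
  genotype-based (trend) tests, and no covariates.
* The grid optimizer guarantees optimality only at its declared
  resolution; the coarse-to-fine strategy can in principle miss a basin
  narrower than the coarse step (the exhaustive mode exists for that).
* Two stages only; no false-discovery-rate design criterion; the
  control:case ratio is an input, not a decision variable.
* The batch-effect model is a uniform frequency scaling of both cases and
  controls in stage 2 — a deliberately crude sensitivity probe, not a
  heterogeneity model.
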