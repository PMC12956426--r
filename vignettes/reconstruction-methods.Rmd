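---
title: "Reconstructing pseudo-IPD from published survival curves by quadratic programming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pseudo-IPD from published survival curves by quadratic programming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survqp)
```

## The problem

Meta-analysis, evidence synthesis and cost-effectiveness modelling often
need individual patient data (IPD) that the source publications do not
provide.  A published Kaplan-Meier plot, however, carries most of the
information: the step curve itself, the numbers-at-risk table printed under
the axis, tick marks at censoring times, and sometimes the total event
count.  *Pseudo-IPD reconstruction* turns these back into per-subject
`(time, status)` rows whose Kaplan-Meier estimate reproduces the published
curve as closely as possible.  The same need arises for competing-risks
studies, where the published curves are cumulative incidence functions
(CIFs) and there has been no established reconstruction method.

## The model

Write the digitized survival values as $s_i$ at times $t_i$,
$i = 1, \dots, N_s$, and let $o_i = 1 - s_i / s_{i-1}$ (with $s_0 = 1$) be
the observed relative decrement.  If $d_i$ subjects fail and $c_i$ are
censored at $t_i$, the Kaplan-Meier construction implies
$o_i r_i = d_i$ with $r_i = N - \sum_{j<i}(d_j + c_j)$.  A reconstruction
is scored by the quadratic criterion

$$W \;=\; \sum_{i=1}^{N_s}\Bigl(o_i\bigl(N - \sum_{j<i}(\tilde d_j + \tilde c_j)\bigr) - \tilde d_i\Bigr)^{2},$$

which is a positive-semidefinite quadratic form in the stacked variables
$(\tilde d, \tilde c)$.  Auxiliary information enters as linear
constraints:

* **numbers at risk** $R_j$ at report times $\tau_j$ give per-period
  equalities $\sum_{i \in C_j} (\tilde d_i + \tilde c_i) = R_{j-1} - R_j$
  over the half-open periods $C_j = \{i : \tau_{j-1} \le t_i < \tau_j\}$
  (the report times are added to the candidate grid so the equalities are
  always satisfiable);
* **total events** give $\sum_i \tilde d_i = N_E$;
* the curve can only drop where someone fails, so $\tilde d_i \ge 1$
  wherever $o_i > 0$, and $\tilde c_i \ge 0$ everywhere;
* **tick marks**: candidate censoring is restricted to the marked times
  (variables eliminated elsewhere), ticks without a visible decrement may
  optionally demand $\tilde c_i \ge 1$.

Minimizing $W$ under these constraints is a quadratic program, solved here
with the dual active-set method of `quadprog::solve.QP` behind
`solve_continuous()`.  A small ridge $\epsilon \sum_i \tilde c_i^2$
(default $\epsilon = 0.001$) makes the objective strictly convex and
resolves the indeterminacy that arises when several tick marks fall
between two event times, preferring evenly spread censorings; the
integerized output is insensitive to $\epsilon$ over
$10^{-4}\text{--}10^{-2}$.

For competing risks the digitized curves are per-cause CIFs $f_{ij}$.  The
increments $o_{ij} = (f_{ij} - f_{i-1,j}) / (1 - \sum_l f_{i-1,l})$ play
the role of the decrements (the Aalen-Johansen construction gives
$o_{ij} r_i = d_{ij}$), the objective sums over causes, and total-event
constraints can be per cause or pooled.  With a single cause the program
is identical to the Kaplan-Meier one on $s = 1 - f$.

### Integerization

The continuous solution is mapped to integer counts by midpoint rounding
of cumulative sums, $\hat d_i = \lfloor 0.5 + \sum_{j \le i} \tilde d_j
\rfloor - \lfloor 0.5 + \sum_{j < i} \tilde d_j \rfloor$ (per cause for
CIFs), which distributes fractional event mass without changing totals.
Censorings are then rescaled within each at-risk period so that the scaled
continuous censorings sum exactly to the leaving count minus the rounded
events, and the same cumulative rounding is applied; because the
period-boundary cumulative sums are integers the floors telescope and
**every period equality holds exactly in the integer output** (asserted,
not approximate).  We deliberately normalize the scale factor by the exact
integer residual rather than by the rounded-event denominator of the
continuous derivation: the two agree whenever rounding leaves the
period's event total unchanged, and the residual form guarantees the
equalities unconditionally.  If rounding makes a period's events exceed
its leaving count, the most rounded-up event cell is decremented (logged).

Remaining subjects never observed to leave are censored at the last grid
time.  When no tick marks are available, the censoring times assigned by
the program are interval-censored in $[t_i, t_{i+1})$, so censored rows
are placed at the interval midpoint $0.5(t_i + t_{i+1})$ by default — the
appropriate convention for subsequent parametric fitting.

### Infeasibility handling

Digitization error can make the constraint system infeasible (e.g. a
leaving count with no candidate slot).  `reconstruct_km()` applies a
logged relaxation ladder: first drop the optional $c \ge 1$ tick
constraints; then reactivate censoring slots at non-tick grid points
inside periods whose equality row lacks capacity; then relax
$d_i \ge 1$ to $d_i \ge 0$ one variable at a time, smallest $o_i$ first.
A hard error is raised only when the equality rows conflict among
themselves.  A presolve step eliminates variables pinned by
single-variable equality rows (common when at-risk counts are reported
densely), which also protects the active-set solver from degenerate,
exactly-tight bound constraints.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.001 | censoring ridge weight (dimensionless); large enough for numerical positive-definiteness, small enough not to distort counts |
| `ridge` | 1e-8 | uniform diagonal added to the objective matrix |
| `force_tick_censoring` | `TRUE` | require one censoring per decrement-free tick; auto-dropped if infeasible |
| `midpoint_censoring` | auto | midpoint placement of censorings when ticks are unavailable |

Time units throughout are the study's own; probabilities are dimensionless.

## The worked example

```{r}
crv <- digitized_curve(c(1, 2, 3), c(0.75, 0.375, 0))
ar  <- at_risk_table(c(0, 2.5), c(4, 1))
reconstruct_km(crv, at_risk = ar, ticks = 1.5)
```

Four subjects: events at 1, 2 and 3, one censoring at the tick.  The
attained $W^* = 0$ says the digitized curve is reproduced exactly.

## What the simulation harness emulates

`simulate_base()`, `simulate_two_arm()` and `simulate_competing()`
generate the evaluation study's three designs:

* single arm, $n = 125$, Weibull hazard
  $h(t) = \lambda^{\alpha}\alpha t^{\alpha-1}$ with shape 0.8 and rate
  0.2, independent Uniform(2, 8) censoring — about 39% censored and about
  76 events per dataset;
* two arms sharing the shape, with the treated arm's hazard multiplied by
  $e^{-0.5}$ (a protective log hazard ratio of magnitude 0.5; the
  evaluation compares paired estimates from the same replicate, so the
  sign convention cannot bias the metrics);
* two competing causes under a Fine-Gray model for cause 1,
  $F_1(t; Z) = 1 - (1 - \kappa(1 - e^{-\lambda_{01} t^{\alpha_1}}))^{\exp(\beta_1 Z)}$
  with $(\kappa, \lambda_{01}, \alpha_1, \lambda_{02}, \alpha_2, \beta_1,
  \beta_2) = (0.6, 0.4, 1.2, 0.2, 1.5, -0.3, 0.3)$ and Uniform(1, 6)
  censoring.  Cause 2 occurs with the complementary long-run probability
  $(1-\kappa)^{\exp(\beta_1 Z)}$ and follows the standard complementary
  design
  $F_2(t;Z) = (1-\kappa)^{\exp(\beta_1 Z)}(1 - \exp(-\lambda_{02} t^{\alpha_2} e^{\beta_2 Z}))$,
  under which cause 1's Fine-Gray fit is correctly specified while the
  cause-2 and cause-specific fits are misspecified — the configuration
  of interest when assessing whether reconstruction distorts each kind
  of estimate.

Observed times (events and censorings) are coarsened *up* to the next
multiple of 0.05, creating ties on purpose; curve values are rounded to 3
decimals to emulate digitizer error.  `emulate_digitization()` then emits
the digitized curve, the tick set (every distinct censoring time), the
at-risk table (at $t = 0, 1, \dots, 8$, or 0..5 for competing risks; pass
`at_risk_times = NULL` for reporting at every observed time) and event
totals.

What the emulator does **not** model: coordinate error on the time axis
(a digitizer also misplaces times), missed or spurious curve points,
plot-resolution limits on dense step regions, and at-risk tables that
disagree with the curve.  Passing tests therefore show fidelity to the
stated error model, not robustness to arbitrary real-world digitization
quality — the monotonicity repair and the relaxation ladder are the
package's containment for such inputs, exercised by the unit tests but
not calibrated against real digitizer output.

## Evaluation metrics

`delta_S()` and `delta_Y()` integrate $|\hat{\hat S}(t) - \hat S(t)|$ and
$|\hat Y(t) - Y(t)|$ (implied number at risk) exactly over $[0, \tau]$
with $\tau$ the maximum follow-up in the true data.  `run_scenario()`
pairs every pseudo-IPD estimate with the estimate from the same
replicate's true IPD — bias and RMSE are with respect to the true-IPD
estimate, not the population parameter — and reports Monte Carlo standard
errors of every summary.  Replicate $r$ always uses seed
`config$seed + r`, so any replicate can be re-run exactly.

## Numerical and design choices

* Ties are handled with the Breslow partial likelihood (coarsening makes
  ties ubiquitous, and Breslow is checkable against hand enumeration);
  the Grambsch-Therneau test uses the identity time transform.
* Fine-Gray fits use censoring weights from the pooled censoring
  Kaplan-Meier (`cmprsk::crr`).
* Half-open period convention $[\tau_{j-1}, \tau_j)$; a grid point at
  exactly $\tau_j$ opens the next period.  Near-duplicate digitized times
  merge within $10^{-9}\times$ the largest time.
* Monotonicity repair clips (running extremum) rather than averages,
  preserving the later point, and drops resulting zero-decrement points
  unless they are tick or at-risk times; when a total-events constraint
  is active, zero-decrement curve points are kept as candidate event
  slots ($d \ge 0$), since a rounded-away step is a plausible event
  location.
* Digitized points after the last at-risk report time form an
  unconstrained tail, subject only to the patient-count cap
  $\sum(d + c) \le N$ (applied to the tail so it is never linearly
  dependent on the period equalities).
* Rounding is deterministic half-up everywhere; there is no stochastic
  tie-breaking anywhere in the pipeline, so reconstructions are exactly
  reproducible.

## Known limitations

* With several tick marks between two event times, the objective cannot
  distinguish allocations of the same censoring total among them; the
  $\epsilon$ ridge resolves this toward equal spread, and the cumulative
  rounding then favors the earlier tick.  When coarsening creates unequal
  true multiplicities the reconstructed censoring pattern can differ from
  the truth even under otherwise exact inputs (the implied survival curve
  is unaffected when at-risk counts pin the risk sets at event times).
  This is the dominant term in the residual curve/at-risk discrepancies
  of the single-arm evaluation.
* When neither event totals nor a covering at-risk table is supplied
  (tick marks only), the criterion is minimized on a flat manifold — any
  censoring total can be compensated by continuous event mass — and the
  $\epsilon$ ridge then suppresses censorings toward their lower bounds,
  overstating late numbers at risk.  Supplying the total event count
  restores identification; reconstructions from ticks alone should be
  treated as qualitative.
* The exhaustive integer oracle (`exhaustive_oracle()`) is for testing
  only and refuses more than 12 free variables; no branch-and-bound MIQP
  is provided.
* Estimation after reconstruction inherits the coarsening: parametric
  fits see times rounded up by up to one resolution step.

## Monte Carlo sizes used by the packaged checks

The evaluation design uses 1000 replicates per scenario, and
`scripts/acceptance.R` runs all of its blocks at that size.  The packaged
test suite uses smaller sizes chosen so the default test run stays quick
on one CPU — 200 replicates for the single-arm accuracy block, 120 for
the two-arm block, 100 for the competing-risks block, and 400 for
generator calibration — and compares summaries at ±3 Monte Carlo
standard errors computed from the replicates actually run.
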