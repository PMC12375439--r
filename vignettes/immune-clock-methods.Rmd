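---
title: "Methods: the immune-clock model and its temporal estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the immune-clock model and its temporal estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoclock)
```

## The reduced PI/AI model

Sepsis immunopathology unfolds on a clock: a hyperinflammatory window in
the first day, a transitional window out to about 72 h, and a largely
irreversible immunosuppressed state beyond it. `immunoclock` models this
with two aggregate state variables — a pro-inflammatory mediator level
$PI(t)$ and an anti-inflammatory level $AI(t)$ — driven by an external
pathogen load $\mathrm{Path}(t)$:

$$\frac{dPI}{dt} = k_{pi}\,\mathrm{Path}(t)
  + k_{pp}\, PI \, H(PI, \theta_{pi}) - d_{pp}\, PI$$
$$\frac{dAI}{dt} = k_{ai}\,\mathrm{Path}(t)
  + k_{ap}\, PI \, H(PI, \theta_{ai}) - d_{ai}\, AI$$

with $H(x,\theta) = x^n/(x^n + \theta^n)$ an activating Hill function.
Time is in hours; mediator levels are in arbitrary concentration units
with the healthy setpoint at $PI_{physio} = AI_{physio} = 1$ in the demo
configuration, since no natural unit exists for these aggregates.

Modelling assumptions worth making explicit:

* **Hill form and exponent.** The activation gate is the standard
  activating Hill function with default exponent $n = 2$ (configurable).
  It is the simplest threshold-encoding form; nothing in the package
  depends on a steeper gate.
* **The AI gate reads PI.** The term $k_{ap} PI\,H(PI, \theta_{ai})$ is
  implemented literally: PI-driven anti-inflammatory production switches
  on when *PI itself* crosses $\theta_{ai}$. This is an unusual structure
  (one might expect the gate to read AI), and it is surfaced prominently
  here because the two readings diverge when $\theta_{ai}$ is large.
* **Pathogen load is an input, not a state.** Three forcing kinds are
  supported: constant, logistic growth with exponential clearance
  switching on at `t_clear` (the default demo forcing: infection grows,
  therapy or clearance removes it), and a sampled series interpolated
  linearly. This captures growth-then-clearance without adding a state
  variable.
* **Boundedness.** For large $PI$, $H \to 1$ and the net PI growth rate
  approaches $k_{pp} - d_{pp}$. The demo parameter set keeps
  $k_{pp} < d_{pp}$ so self-amplification is transient and trajectories
  stay bounded; parameter sets with $k_{pp} > d_{pp}$ are legitimate for
  equilibrium analysis ([steady_states()]) but diverge under sustained
  forcing.

### Numerics

Integration uses deSolve's adaptive solvers (default `lsoda`, relative
tolerance $10^{-8}$). The vector field is evaluated on the clamped state
$\max(x, 0)$ and solutions are clamped at zero after solving, with the
number of clamped grid values recorded — with non-negative forcing the
flow leaves the positive quadrant invariant, so clamping events indicate
numerical round-off only. Self-convergence of the demo scenario between a
0.1 h and a 0.001 h grid is below $10^{-4}$ in sup-norm, which is the
tolerance the tests pin.

Equilibria are found by damped Newton iteration (numerical Jacobian,
step-halving line search) from a deterministic grid of starting points;
each reported root is verified by substitution ($|\dot{PI}|, |\dot{AI}| <
10^{-8}$) and classified by the eigenvalues of the Jacobian. Because the
AI equation is linear in AI given PI, starts are seeded with the
closed-form $AI^*(PI)$.

### Phase classification and onset timing

A state is *homeostatic* when both coordinates lie within a band of
half-width 0.25 (demo default) around the setpoint. Outside the band the
balance ratio $R = PI/(AI + \varepsilon)$ classifies the state:
hyperinflammatory above 2, immunosuppressive below 0.5, transitional
between (both thresholds configurable). The anti-inflammatory onset
$t_{ai}$ is the earliest time AI reaches a fraction $q$ (default 0.1) of
its trajectory maximum, linearly interpolated; the threshold fraction is
a definition the package fixes, since "initiation" has no canonical
cut-off.

### Parameter fitting

`fit_parameters()` minimises the stacked PI/AI residual sum of squares
with bounded Levenberg–Marquardt (minpack.lm), multi-started from the
user's guess plus log-normal jitter drawn from a fixed internal RNG
stream (so fits are reproducible and do not disturb the caller's RNG).
Ties are broken by residual, then by parameter L2 norm. All-zero
observations under zero forcing fit any parameter set; this degeneracy is
detected and flagged (`non_identifiable`) rather than "solved". Under
the demo forcing, all six rate constants are identifiable: noiseless
recovery is exact to $<10^{-6}$ relative error, and with 5% observation
noise at 200 time points the rates return within a few percent (the test
suite asserts 1% and 15% respectively).

## The stochastic extension

`simulate_sde()` integrates $dX = f(X,t)\,dt + \sigma(X)\,dW$ by
Euler–Maruyama on a fixed-step grid, with $f$ the clock vector field and
diffusion either additive $(\sigma_{pi}, \sigma_{ai})$ or multiplicative
$(\sigma_{pi} PI, \sigma_{ai} AI)$. Multiplicative is the default: it
keeps relative fluctuation scale-free and respects the zero boundary.
Negative excursions are reflected by clamping, and the number of clamped
increments is reported (zero when noise is zero). Ensembles are pure
functions of `(seed, n_paths, grid, configs)`.

Two numerical caveats the tests encode:

* **Reflected variance law.** A path started *at* the boundary with unit
  additive noise has $\mathrm{Var}(X_t) = (1 - 2/\pi)\,t$, the reflected
  Brownian law — not $t$. Started far from the boundary, the slope is 1.
* **Small-noise validity of the mean check.** With a nonlinear drift the
  ensemble mean differs from the ODE solution by an $O(\sigma^2)$ Jensen
  term that no number of paths removes. The "ensemble mean within 3
  Monte-Carlo standard errors of the ODE" check is therefore run in the
  regime where that term is below sampling error: at 500 paths and step
  0.01 h this bounds $\sigma$ at about 0.03 for the demo scenario
  (measured shift/SE: 4.5 at $\sigma=0.1$, 3.1 at 0.05, 2.1 at 0.03).
  The package's default noise level (0.05) is a modelling default, not a
  test condition.

Stage occupancy maps each path-time point to *reversible* (inside the
homeostasis band), *stable* (outside the band and moving slower than
`rate_tol` = 0.02 units/h), or *transitional* (otherwise), summarised
over the three-stage partition 0–24 / 24–72 / >72 h. This mapping from
PI/AI states to the named kinetic stages is the package's own
construction; the stage *boundaries* are the clock's phase boundaries.
Reversibility is the fraction of paths whose final in-band stretch begins
at or before the horizon, with a Wilson 95% interval.

## Intervention timing

The objective is
$$t^* = \arg\min_{t \in [t_0, t_1]} \{ L(PI(t), AI(t)) + \lambda C(t) \},
\qquad L = |PI - PI_{physio}| + |AI - AI_{physio}|,$$
with burden $C(t)$ constant, linearly increasing over the window, or a
user table, and $\lambda \in [0,1]$ weighing safety against efficacy. The
default window is 0–72 h.

Two modes are exposed because the formula and its clinical reading pull
in different directions. *Pointwise* mode (default) evaluates $L$ on the
uncontrolled trajectory at $t$ — the literal objective: intervene when
the system is least imbalanced and burden is acceptable. *Counterfactual*
mode re-simulates from $t$ with a named intervention active and scores
the mean imbalance over the aftermath plus $\lambda C(t)$ — intervene
where intervening helps most. The mode is recorded in every result.

The solver scans a 0.1 h grid, refines the minimiser locally
(`stats::optimize()` in pointwise mode), breaks ties by the earliest
time (earlier intervention is clinically preferred), and reports
near-optimal windows: maximal grid intervals within $\epsilon$ of the
minimum, $\epsilon$ defaulting to 5% of the objective's range over the
window since no published criterion defines the reported windows' edges.
Exhaustive 0.001 h scans agree with the solver to within one coarse grid
step across 50 randomised scenarios in the test suite.

Interventions are time-windowed parameter multiplications. Two presets
ship: `myd88_blockade` (innate-axis blockade: scales $k_{pi}$ and
$k_{pp}$ by 0.2 while active) and `checkpoint_blockade` (scales $k_{ap}$
by 0.2 and $d_{ai}$ by 1.5). The mapping from drug classes to parameter
factors is a modelling construction with configurable factors, not a
measured pharmacology.

## Temporal estimators

* **QC filter**: keep cells with ≥ 200 detected genes *and* ≤ 20%
  mitochondrial fraction (both configurable); the removal report counts
  each rule separately and jointly, and an empty result warns rather than
  errors. The filter is idempotent.
* **Pseudotime calibration**: the unique increasing linear map through
  two (hour, unit) anchors — e.g. 16 h → 6.8 and 27 h → 10.2 units —
  with exact inversion.
* **Branch detection**: cells are binned by hour; per bin, one- and
  two-component Gaussian mixtures (mclust) are fitted to the scores on
  the bin's leading principal direction. Evidence is the classical
  BIC(1) − BIC(2) (positive favours a split), gated by a standardised
  mean separation of at least `gate_sd` (default 1) pooled
  within-component sd. The branch hour is the first bin midpoint whose
  gated evidence is positive *and stays positive in all later bins* — a
  persistence requirement that suppresses transient false splits (false
  detections on 20 branchless datasets: ≤ 5% in the test suite). The
  confidence half-width is a within-bin bootstrap over cells (default
  500 resamples; 200 where runtime matters).
* **Exhaustion staging**: half-open intervals at 24 / 72 / 120 h with a
  marker gate in the early window; the unnamed gaps (48–72, 96–120 h)
  belong to the earlier stage.
* **Peak fold change**: ratio of window means (peak vs baseline), with
  non-overlap and positive-baseline validation.
* **Lead–lag**: Pearson cross-correlation over integer-step lags up to
  `max_lag`, refined by parabolic interpolation around the discrete
  argmax — sub-grid resolution matters because the target lead (4.3 h)
  need not be a grid multiple.
* **Depletion-rate ratio**: per-trajectory least-squares slopes of
  pseudotime on hours, ratio of group means, percentile bootstrap CI
  over subjects. The ratio is computed per trajectory (per subject), the
  natural unit when cohorts are compared.
* **Severity correlation**: sample Pearson r with the Fisher-z 95%
  interval.

## What the generators emulate — and what they do not

Every generator is a pure function of a `synth_config()` (identical
config ⇒ identical output) and returns the truth it generated from, so
estimator tests close the loop. Defaults equal the calibrated effect
sizes the estimators target — branch at 22 h, an 8.4-fold exhaustion
pulse peaking at 42 h, a 4.3 h epigenetic lead, a 2.3-fold rate ratio,
and 0.63 severity coupling — so recovery tests read their expected
values from the config.

Choices that required judgement:

* **Bifurcation geometry.** Features are Gaussian around a mean that
  drifts slowly along a maturation axis (0.05 units/h); after the branch
  each cell belongs to one of two fates whose means separate at 2
  units/h along a fate axis, with within-fate sd 0.6. The divergence is
  *asymmetric* — the M1-like program departs while the M2-like fate
  retains the progenitor profile — matching the M1-dominated early
  phase. This matters statistically as well as biologically: with
  symmetric arms, the bin containing the branch is a symmetric
  centre-plus-arms mixture whose best two-Gaussian fit is a *scale*
  mixture with coincident means, so no mean-separation gate can fire
  there and detection is systematically one bin late. With asymmetric
  divergence the half-split bin is a genuine two-location mixture; a
  calibration sweep (40 replicate fits per setting, seeds disjoint from
  any test seed) put branch-bin detection probability at 1.00 for
  rate 2.0 / sd 0.6.
* **Exhaustion pulse shape** is Gaussian in time (centre 42 h, sd 6 h),
  with centre amplitude $(\text{fold}-1)\times$ baseline. Only the peak
  window and fold are anchored; the shape is the package's choice. The
  mean of the pulse over a finite window is below its centre value, so
  the truth record carries a closed-form `fold_window()` for any window
  pair — the windowed 36–48 h fold at defaults is 7.33, about 13% below
  the centre fold 8.4 — and tests compare against it.
* **Lead–lag latent signal** is a logistic activation at 20 h plus a
  late Gaussian pulse: smooth, asymmetric, with enough curvature that
  the cross-correlation peak is well defined. Both channels add
  independent Gaussian noise (sd 0.05).
* **Depletion cohort.** Subject slopes are normal within group (control
  mean 1 unit/h, sepsis mean 2.3, CV 0.15); subject-level (slope, score)
  pairs are drawn jointly *before* trajectory noise. Scores are
  $\mu_s + \sigma_s(\rho z + \sqrt{1-\rho^2}\,\varepsilon)$ with $z$ the
  slope standardised under the pooled two-group mixture law, giving
  *exact population correlation* $\rho = 0.63$ with the latent rate —
  the pooled slope distribution is a two-component mixture, not a
  normal, so this construction rather than a textbook bivariate normal
  guarantees the target correlation.
* **Spread parameters** quoted as "± x" in the anchoring literature are
  of ambiguous type; the generator treats its own spreads as standard
  deviations, all configurable.

The generators deliberately do **not** model scRNA-seq count statistics:
no zero inflation, library-size variation, batch structure, doublets, or
dropout. Passing recovery tests therefore demonstrates that the
estimators recover the *temporal statistical structure* they target at
realistic effect sizes and noise — not that they are robust to the full
technical noise of real single-cell data, which would require upstream
normalisation this package intentionally leaves out of scope.

## Problem sizes used by the checks

The reference conditions the tests and the acceptance script run at:
2,000 cells × 20 features in 12 bins with a 200-resample bootstrap for
branch detection; a 289-point 0.25 h grid for lead–lag; 100 trajectories
per group × 5 time points with a 500-resample bootstrap for the rate
ratio; 200 subjects for the severity correlation; 200 observation times
for parameter recovery; 500 paths at step 0.01 h for ensemble checks;
50 scenarios against 0.001 h exhaustive scans for the optimiser. These
sizes make every check reproducible on a single CPU in minutes while
leaving Monte-Carlo margins comfortably inside the asserted tolerances.

## Known limitations

* The two-state reduction has no damage, effector or suppressor state;
  regimes where those feed back on the mediators are outside the model.
* Euler–Maruyama is first-order; no Milstein or exact schemes.
* The branch detector assumes the split is visible on the leading
  principal direction within a bin; splits orthogonal to the dominant
  variance direction would need more components or directions.
* `classify_phase` thresholds and the homeostasis band are heuristics to
  be calibrated per application; the defaults are demo values.
* Counterfactual optimisation re-integrates the ODE per candidate time;
  use a coarser candidate grid (e.g. 1 h) when this matters.
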