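# immunoclock

Sepsis immunity runs on a clock: a hyperinflammatory surge over the first
day, a transitional phase to about 72 h, then a largely irreversible
immunosuppressed state. Where a patient sits on that clock decides whether
an intervention helps or harms — the same drug that damps an early cytokine
storm deepens late immune paralysis. `immunoclock` is an R package for
working with this temporal structure quantitatively: it is aimed at
computational immunologists and systems-biology modellers who need a
tested, reproducible implementation of the clock's dynamical core and of
the timing estimators used on single-cell style data.

The package provides:

* **A reduced dynamical model** of aggregate pro-inflammatory (PI) and
  anti-inflammatory (AI) mediator levels, forced by an external pathogen
  load, with Hill-gated self-amplification:

  $$\dot{PI} = k_{pi}\,\mathrm{Path}(t) + k_{pp} PI\, H(PI,\theta_{pi}) - d_{pp} PI$$
  $$\dot{AI} = k_{ai}\,\mathrm{Path}(t) + k_{ap} PI\, H(PI,\theta_{ai}) - d_{ai} AI$$

  with $H(x,\theta)=x^n/(x^n+\theta^n)$ — plus equilibria with stability,
  phase classification, anti-inflammatory onset timing $t_{ai}$, and
  bounded multi-start least-squares parameter fitting.
* **A stochastic extension** (Euler–Maruyama path bundles, additive or
  multiplicative noise) with stage-occupancy and reversibility-probability
  summaries over the 0–24 / 24–72 / >72 h partition.
* **An intervention-timing optimiser** minimising
  $L(PI(t),AI(t)) + \lambda C(t)$ over a window, where
  $L = |PI-PI_{physio}| + |AI-AI_{physio}|$ and $C$ is the treatment
  burden, with near-optimal window extraction and named intervention
  presets realised as time-windowed parameter modulations.
* **Temporal estimators** for cell-by-feature inputs: QC filtering
  (≥ 200 genes, ≤ 20% mitochondrial), linear pseudotime calibration,
  time-binned bifurcation detection by Gaussian-mixture BIC evidence with
  persistence gating, exhaustion staging, peak fold-change, lead–lag by
  lagged cross-correlation, depletion-rate ratios, and severity
  correlations.
* **Seeded synthetic-data generators** reproducing the temporal effect
  sizes the estimators target (branch at 22 h, 8.4-fold exhaustion pulse,
  4.3 h epigenetic lead, 2.3-fold depletion acceleration, r = 0.63
  severity coupling), each carrying its ground truth.
* **Evidence-synthesis helpers**: equal-weight macro-averages, relative
  improvements, and PRISMA flow accounting with consistency verdicts.

See `vignettes/immune-clock-methods.Rmd` for the model assumptions,
numerical choices and generator design.

## Worked example

```r
library(immunoclock)

params <- clock_params(kpi = 0.8, kpp = 0.3, dpp = 0.45,
                       kai = 0.1, kap = 0.35, dai = 0.2,
                       theta_pi = 1.2, theta_ai = 1.5)
path <- pathogen_load("logistic_with_clearance", P0 = 0.05, g = 0.4,
                      K = 3, t_clear = 20, c_clear = 0.15)
traj <- integrate_clock(params, path, c(t = 0, PI = 0, AI = 0),
                        seq(0, 96, by = 0.1))
traj
#> Immune-clock trajectory: 961 states over 0-96 h
#>   final PI=8.956e-05 AI=0.0001961; clamped states: 0

anti_inflammatory_onset(traj)
#> [1] 11.55276
```

The infection grows logistically, clearance starts at 20 h, and both
mediators return toward zero by 96 h; the anti-inflammatory response
initiates (reaches 10% of its peak) at $t_{ai} \approx 11.6$ h — in the
prognostically favourable early range.

```r
cfg <- cost_config(lambda_weight = 0.5, burden_kind = "linear_increasing",
                   t0 = 0, t1 = 72)
optimal_time(traj, cfg)
#> Optimal intervention time: t* = 7.963 h (objective 0.79915, pointwise mode)
#> Near-optimal windows (epsilon = 1.294):
#>   0.00-10.80 h
#>   47.70-58.00 h
```

With equal weight on imbalance and a burden that grows with delay, the
optimum sits at ~8 h — inside an early near-optimal window (0–10.8 h),
with a second, inferior window after the inflammatory peak subsides.

```r
cells <- gen_bifurcating_cells(synth_config(seed = 7))
est <- detect_branch_point(qc_filter(cells$cells)$filtered,
                           cells$truth$time_bins, n_boot = 200, seed = 7)
est
#> Estimated bifurcation at 22.00 h (bootstrap half-width 2.00 h, 200 resamples)
```

A 2,000-cell synthetic matrix with a fate split injected at 22 h is QC
filtered and scanned in 4 h bins; the mixture-evidence detector recovers
the branch at 22 h with a 2 h bootstrap half-width.

A scriptable front end over the same functions is included
(`inst/cli/immunoclock.R`; subcommands `simulate`, `sde`, `optimize`,
`fit`, `synth`, `detect-branch`, `estimate`, `evidence`).

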