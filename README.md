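# granmotion

Single-granule motility analysis for live-cell particle tracking:
mean-square-displacement (MSD) model fitting and five-class motion sorting,
with a synthetic trajectory/movie generator so the whole pipeline is
testable without microscope data.

## The problem

Cytotoxic lymphocytes kill their targets by transporting **lytic granules**
(secretory lysosomes) to the immunological synapse. How a granule moves —
sitting still, diffusing, being hauled along microtubules, or rattling
inside an actin cage — is read off from single-particle tracking: granules
are imaged by spinning-disk confocal microscopy in 3D (stacks of 40 × 0.2 µm
planes at 1 s/stack) or by TIRF in 2D at the plasma membrane (100 ms/frame),
detected and linked into trajectories, and each trajectory's time-averaged
MSD

```
MSD(nΔt) = ⟨ |r(t + nΔt) − r(t)|² ⟩ₜ
```

is fitted with three diffusion models (2D: 4DΔt; 3D: 6DΔt; `k` is the
constant offset produced by finite localization accuracy):

| model    | MSD(Δt) | signature |
|----------|---------|-----------|
| random   | `2·dim·D·Δt + k` | straight line |
| directed | `2·dim·D·Δt + (vΔt)² + k` | upward curvature |
| caged    | `R²·[1 − a₁·exp(−2·dim·a₂·D·Δt/R²)] + k`, a₁=0.99, a₂=0.85 | plateau near R² |

Each track is then sorted into one of **five motion classes** by, in order:

1. **immobile** — max MSD within the 50 s observation window ≤ 0.2 µm²
   (the 95th percentile of per-track max MSD in fixed cells; recalibratable
   with `calibrate_immobile_threshold()`);
2. **complex** — all three fits have r² < 0.33;
3. **random** — the three r² agree to within sd < 0.015 (guards against the
   extra-parameter models winning on nearly linear MSDs);
4. otherwise the best-r² model wins (**directed** / **caged** / **random**).

Track geometry (length = Σ step displacements, displacement = |end − start|,
straightness = displacement/length, speed) is summarized per condition as
histograms, cumulative probability distributions, mean/median ± SEM, and
compared by Student's t-test or the Kolmogorov–Smirnov test.

Because real granule-tracking data for this workflow are not publicly
deposited, the package includes a first-class simulator (`trajsim`) of all
four kinematic regimes at granule scale (D ~ 0.001–0.05 µm²/s,
v ~ 0.05–0.3 µm/s, R ~ 0.2–1 µm, Gaussian localization noise) plus a movie
renderer, spot detector and nearest-neighbor linker (`imaging`), so every
stage is tested against ground truth.

## Worked example

```r
library(granmotion)

spec <- data.frame(
  model     = c("immobile", "random", "directed", "caged"),
  count     = 50,
  D         = c(0,    0.02, 0.005, 0.05),   # µm²/s
  v         = c(0,    0,    0.15,  0),      # µm/s
  R         = c(NA,   NA,   NA,    0.4),    # µm
  sigma_loc = 0.02, n_steps = 50, dt = 1)
cohort <- simulate_cohort(spec, seed = 7)

cl <- classify_cohort(cohort$trajectories)
print(cl$fractions, digits = 2)
#>   condition immobile random directed caged complex  n
#> 1     caged     0.76   0.02     0.02  0.04    0.16 50
#> 2  directed     0.00   0.00     1.00  0.00    0.00 50
#> 3  immobile     1.00   0.00     0.00  0.00    0.00 50
#> 4    random     0.00   0.42     0.24  0.34    0.00 50
```

Immobile and directed regimes are recovered essentially perfectly. The
caged and random rows show the two *structural* limits of the published
thresholds, not bugs: a 0.4 µm cage's MSD plateau (≈ 1.2·R² ≈ 0.19 µm²)
sits below the 0.2 µm² immobility bound, so most caged tracks are labelled
immobile; and single-track MSD noise at 50 steps makes the three r² differ
by far more than 0.015, so Brownian tracks are often won by the
extra-parameter models. Both effects are analyzed in the vignette.

```r
tm    <- metrics_table(cohort$trajectories, window_s = 10)  # first 10 s
s_dir <- summarize_condition(tm, cl$table, "directed")
print(s_dir$stats[, c("metric", "mean", "median", "sem")], digits = 3)
#>                          metric  mean median     sem
#> length_um             length_um 2.112  2.143 0.03568
#> displacement_um displacement_um 1.509  1.529 0.04259
#> straightness       straightness 0.712  0.721 0.01436
#> speed_um_s           speed_um_s 0.211  0.214 0.00357

s_imm <- summarize_condition(tm, cl$table, "immobile")
cmp <- compare_conditions(s_dir, s_imm, "length_um", test = "ks")
sprintf("KS D = %.3f, p = %.3g", cmp$statistic, cmp$p_value)
#> "KS D = 1.000, p = 1.98e-29"
```

Directed tracks cover ~2.1 µm in their first 10 s at straightness ~0.7;
their length distribution is completely separated from the immobile pool
(KS D = 1). Per-track fits expose the parameters:

```r
fit <- fit_msd_models(compute_msd(cohort$trajectories[[120]]))  # directed
print(fit)
#> <msd_fit random> D=0.06687 k=0 r2=0.8727
#> <msd_fit directed> D=0.007549 v=0.1392 k=0 r2=0.9999
#> <msd_fit caged> D=0.0806 R=6.229 k=0 r2=0.8111
```

(truth: v = 0.15 µm/s, D = 0.005 µm²/s).

## Pipeline and CLI

`run_pipeline(pipeline_config(...))` chains
simulate → filter (≥ 6 steps, optional membrane-proximal exclusion) →
MSD/fits → classify → metrics → report, writing one tab-delimited table per
stage plus a provenance manifest; identical configuration and master seed
reproduce byte-identical outputs. The same stages are available as CLI
subcommands:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/granmotion.R", package="granmotion"))')
Rscript $CLI simulate --config sim.cfg --out trajs.tsv --seed 9
Rscript $CLI classify --in trajs.tsv --out labels.tsv
Rscript $CLI run --config sim.cfg --out-dir run1 --seed 9
```

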