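---
title: "Granule motility analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granule motility analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granmotion)
```

## The measurement model

A tracked granule is an ordered sequence of positions $r(t_i)$ in µm, in 2D
(TIRF, typically 100 ms/frame) or 3D (spinning-disk stacks, typically
1 s/stack with 0.2 µm axial steps). Reported positions are the true
positions plus localization error, modelled as i.i.d. Gaussian noise of
per-axis standard deviation $\sigma_{loc}$ — the standard model for
centroid-localization error, whose visible consequence is a constant
offset $k$ added to the MSD at every lag.

`compute_msd()` estimates the time-averaged MSD over *all* ordered index
pairs at each integer frame lag $n$:

$$\mathrm{MSD}(n\Delta t) = \frac{1}{|P_n|}\sum_{(i,j)\in P_n}
  |r(t_j) - r(t_i)|^2, \qquad P_n = \{(i,j): f_j - f_i = n\},$$

where $f_i$ are integer frame indices on the track's base interval. Missing
frames (linker gaps) are handled by pair exclusion: a lag's average uses
only the pairs actually observed, and the pair count $n_{pairs}$ per lag is
retained as the fit weight.

Three motion models are fitted to each curve, with all parameters
constrained non-negative (prefactor $2\,\mathrm{dim}$, i.e. $4D\Delta t$ in
2D and $6D\Delta t$ in 3D):

* random: $\;2\,\mathrm{dim}\,D\,\Delta t + k$
* directed: $\;2\,\mathrm{dim}\,D\,\Delta t + (v\Delta t)^2 + k$
* caged: $\;R^2\!\left[1 - a_1 e^{-2\,\mathrm{dim}\,a_2 D \Delta t / R^2}\right] + k$,
  with $a_1 = 0.99$, $a_2 = 0.85$ (the standard series approximation for
  diffusion confined to a region of radius $R$; $D$ is here the
  within-cage diffusion coefficient).

The exact printed forms of these equations in the literature vary in the
dimensional prefactor; the forms above are the dimensionally forced
standard, and the prefactor is overridable (`fit_msd_models(prefactor=)`)
for comparison with non-standard conventions.

## The five-class decision procedure

`classify_track()` applies, in order:

| rule | condition | class |
|------|-----------|-------|
| 1 | max MSD over all lags within the 50 s observation window ≤ 0.2 µm² | immobile |
| 2 | all three $r^2 < 0.33$ | complex |
| 3 | sd of the three $r^2 < 0.015$ | random |
| 4 | otherwise | best-$r^2$ model |

The defaults (0.2 µm², 50 s, 0.33, 0.015) are the published operating
points of this procedure; the immobility bound is defined as the 95th
percentile of per-track maximum MSD in chemically fixed cells and can be
recalibrated from any fixed-cell track population with
`calibrate_immobile_threshold()`. Rule 3 exists because the directed and
caged models strictly contain the random model: on a nearly linear MSD
their extra parameters always buy a marginally higher $r^2$, so near-ties
are resolved *for* the simpler model. Exact $r^2$ ties in rule 4 are broken
by parsimony (random, then caged, then directed). A fit whose optimizer
fails carries $r^2 = -\infty$: it loses every comparison, and if all three
fail the track is complex (with a warning).

Two asymmetries are deliberate. The immobility test (rule 1) uses the
*full-lag* MSD curve — "never exceeds the bound within the observation
window" is a statement about the whole trajectory — while model fitting
uses lags up to half the track duration, because long-lag MSD estimates
average very few pairs and are dominated by noise. And tracks shorter than
the 50 s window are tested on the lags they have.

## What the simulator states, and what a green test establishes

`simulate_trajectory()` generates the four regimes exactly as the analysis
assumes them: Brownian increments of per-axis variance $2D\,dt$; constant
drift $v\,dt$ added for directed motion; radial reflection at a sphere/disc
of radius $R$ for caged motion (a reflecting boundary adds no parameters
and has the uniform distribution as its stationary state); no motion for
immobile granules; i.i.d. Gaussian noise of s.d. $\sigma_{loc}$ added to
every reported coordinate. Defaults follow the acquisition geometry
(dt = 1 s in 3D, 0.1 s in 2D) and granule-scale magnitudes
(D ~ 0.001–0.05 µm²/s, v ~ 0.05–0.3 µm/s, R ~ 0.2–1 µm); since no
measured granule parameter values are published, these are chosen once for
regime separability at those scales and are user-overridable everywhere.
Seeding is hierarchical (one master seed, per-row and per-track child seeds
by counter), so cohorts reproduce independently of generation order.

The generator deliberately omits: photophysics (blinking, bleaching),
anomalous (fractional) diffusion, stage drift, fixation wobble, and
within-track regime switching ("complex" motion is by definition a fit
failure, not a generative model; composite tracks are exercised in tests
by concatenation). A green parameter-recovery or classification test
therefore establishes that the *estimators and decision rules* behave as
documented on data satisfying their own assumptions — not that those
assumptions hold in any particular cell.

The movie renderer draws each granule as an isotropic Gaussian intensity
profile (argument `psf_sigma`, in µm) on a constant background with
optional Poisson noise; detection is band-pass filtering plus
intensity-weighted center of mass in a window matched to the 0.3 µm
estimated diameter; linking is greedy mutual-nearest-neighbor with
max distance 0.5 µm per frame interval, gap closing across ≤ 2 missing
frames (search radius scaling with the gap), and a ≥ 6-step filter. A gap
size quoted in µm for a frame-valued tracking parameter is dimensionally
inconsistent; it is interpreted as 2 frames, and a µm-valued bridging
radius remains available through `linking_config()`. Movies live in memory
as plain arrays (with a text serialization in the CLI): no TIFF library is
assumed.

## Numerical choices

* **Weighted fits.** Least squares weighted by the pair count per lag; the
  same weights enter $r^2 = 1 - SS_{res}/SS_{tot}$ (about the weighted
  mean). The coefficient of determination — not a squared correlation — is
  used because the sorting rules need wrong *shape* to be penalized.
* **Linear models solved exactly.** The random and directed models are
  linear in $(D, v^2, k)$; non-negative least squares is solved by
  active-set enumeration (≤ 3 parameters, exact, no iterative tolerance).
* **Caged model.** Bounded quasi-Newton (L-BFGS-B) with analytic gradient
  from three starts — plateau estimate (mean of the last 3 MSD points) with
  $D$ from the first lag, and ×10/÷10 perturbations of $D$ — followed by a
  Nelder–Mead polish; on noise-free model curves parameters are recovered
  to ~1e−8 relative. Non-convergence yields the $-\infty$ sentinel and
  never aborts the other fits.
* **Fit range.** Lags up to half the track duration, and at least 5
  retained lags; with the default fraction this means tracks need ≥ 10
  steps to be fittable, while the keep filter admits tracks at 6 steps —
  6–9-step tracks pass filtering but are rejected at fitting with a named
  error, by design of both rules.
* **Track metrics.** Length, displacement, straightness
  (displacement/length, defined as 0 for zero-length tracks), mean speed;
  the 10-s variant truncates to the *first* 10 s of each track (a single
  per-track value, not a sliding or segment average — the least-surprising
  reading of a per-track "during 10 s" quantity).
* **Membrane filter.** The manual region-of-interest step of interactive
  software is replaced by a programmable signed-distance membrane model
  (default: a plane); a track is removed whole if *any* point comes within
  0.2 µm of the membrane, because clipping points would bias the MSD.
* **Statistics.** Student's (pooled-variance) two-sided t-test for
  normal-like metrics; the two-sample KS test for exponential-like ones,
  with the D statistic computed from the package's own ECDFs. "Median ±
  SEM" is a nonstandard estimator pairing, so condition summaries report
  both the SEM and a seeded bootstrap SE of the median (1000 resamples).
  No multiple-testing correction is applied, and none is claimed.
* **Determinism.** All tables are written with locale-independent %.15g
  formatting; the pipeline manifest contains no timestamps, so a fixed
  master seed reproduces byte-identical run directories.

## Known limitations: where the published thresholds break

Two acceptance checks are deliberately left failing, because they encode
properties the stated operating points do not have.

**A 0.4 µm cage is "immobile" by the MSD bound.** For reflected Brownian
motion in a sphere of radius $R$ the stationary distribution is uniform,
so the long-lag MSD plateau is $E|r_1 - r_2|^2 = \tfrac{6}{5}R^2$ (plus
$2\,\mathrm{dim}\,\sigma_{loc}^2$). At $R = 0.4$ µm that is ≈ 0.19 µm² —
*below* the 0.2 µm² immobility bound — so a majority of such caged tracks
never exceed the bound within 50 s and are labelled immobile by rule 1
(~76–85% in our cohorts). Cages with $R \gtrsim 0.45$ µm escape the bound;
the overlap of "caged" and "immobile" below that scale is a property of
the thresholds, not of the implementation.

**Single-track $r^2$ values are too noisy for the 0.015 override at
50 steps.** The time-averaged MSD of one 50-step Brownian track wanders
with relative standard deviation $\sim\sqrt{n/(N-n)}$ at lag $n$; the
directed and caged models genuinely fit that wander better or worse than a
line by far more than 0.015 in $r^2$-sd. Rule 3 therefore rarely fires,
and roughly half of Brownian tracks are won by an extra-parameter model
(~40–60% labelled random). The override becomes effective only for much
longer tracks or ensemble-averaged curves.

**Pure localization noise does not reach a 0.2 µm² fixed-cell threshold.**
With $\sigma_{loc} = 0.05$ µm (3D, 50 steps) the 95th percentile of
per-track maximum MSD is ≈ 0.04 µm² — reproducible across seeds to a few
percent, but a factor ≈ 5 below 0.2 µm². A fixed-cell bound of 0.2 µm²
implies additional apparent motion (stage drift, fixation wobble, worse
effective localization) that the noise-only generator excludes by design.
Users calibrating on their own fixed-cell data will get a threshold
matched to their setup; the 0.2 µm² default is retained as the published
operating point.

Other limitations: no anomalous-diffusion exponent fitting, no
per-segment motion-state switching (HMM), no turning-angle or
velocity-autocorrelation analyses, no deconvolution or drift correction in
the imaging front end, and no TIRF-optics depth inference — the 2D movie
path is a z-collapsed projection.
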