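---
title: "Methods and design of the clotmetrics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the clotmetrics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotmetrics)
```

`clotmetrics` quantifies fibrin clot formation, structure and dissolution from
five laboratory modalities: plate-reader turbidimetry, pressure-driven
permeation, oscillation rheometry, electron-micrograph morphometry, and
coagulometer clottability courses.  Each modality has a seeded synthetic
generator with exact ground truth, so the analysis code can be validated by
parameter recovery rather than by fixed reference files.  This vignette
records the models, the tunable parameters and the numerical decisions, and
what the synthetic validation does — and does not — establish.

## Turbidimetric waveform metrics

A clotting well rises in 340 nm absorbance as protofibrils assemble into
light-scattering fibers, and falls again when a fibrinolytic protease digests
the network.  The metrics are defined on the waveform itself:

* `a_max` — maximal turbidity above baseline, the classical proxy for fiber
  mass/length ratio;
* `ct50`, `ct90` — times to reach 50% / 90% of `a_max` on the ascending
  branch, measured from time zero;
* `lt50` — time for turbidity to fall to half of `a_max` on the descending
  branch, measured from time zero when the protease is present from the start
  (*intrinsic* lysis) or from the addition time when it is layered onto a
  formed clot (*extrinsic* lysis).

Numerical decisions:

* **Threshold crossings use linear interpolation** between samples.  This
  gives sub-interval resolution and is deterministic; the first crossing in
  the relevant direction wins, which is the tie-break that matters on noisy
  descending branches.
* **Baseline defaults to the first reading**, overridable when a blank is
  available.
* **Smoothing is off by default.**  An optional centered moving average (odd
  window, `smooth_window`) is provided because noise makes a shallow
  descending branch cross half-max repeatedly; a window of 5 samples (50 s at
  the default 10 s interval) keeps median CT50/LT50 recovery errors below one
  sampling interval up to 2% amplitude noise.  When smoothing is requested,
  the peak is located on the same smoothed signal as the crossings so the
  invariant `ct50 <= ct90 <= t_amax` survives noise.
* **Minimum clotting amplitude** is 0.05 AU by default: traces that never
  rise that far above baseline raise a `no_clotting` condition rather than
  returning meaningless times.
* Whether a plasma-clot "clotting time" should be read as CT90 or CT50 is a
  reporting convention, not a computation; both are always computed and the
  report column is chosen in `study_config()`.

The generator builds the waveform as the pointwise minimum of two logistic
branches, rescaled so the sampled maximum equals the programmed `a_max`
exactly.  With the default branch separation, the half-maximum crossings sit
at the programmed `ct50_true`/`lt50_true` to within microseconds, far below
the 10 s sampling interval (plate-reader read intervals are not standardized
across instruments, so 10 s was fixed once as a typical cadence).  Noise
is additive i.i.d. Gaussian on absorbance — the simplest defensible
plate-reader model; real wells also drift and bubble, which the generator
does not emulate, so green recovery tests establish correctness of the metric
extraction, not robustness to every laboratory artifact.

## Permeation and the Darcy constant

Buffer driven through a clot of length $L$ and cross-section $A$ by a
hydrostatic pressure drop $\Delta P$ permeates a volume $Q$ in time $t$; the
permeation coefficient is

$$K_s = \frac{Q\,\eta\,L}{t\,A\,\Delta P} \quad [\mathrm{cm}^2],$$

with $\eta$ the buffer viscosity.  The assay constants default to
$\eta = 10^{-7}\,\mathrm{N\,s/cm^2}$, $L = 1.5$ cm, $A = 0.09$ cm²,
$\Delta P = 0.170$ N/cm².  $Q$ is obtained from the mm advance of the liquid
front in the collection tubing, $Q = \pi (d/2)^2 \times \mathrm{length}$; the
tubing inner diameter $d$ is apparatus-specific and deliberately has **no
default** — it must be supplied, and the generator documents its own value
(0.2 cm).

$t$ is taken over the full QC-passing window (per-interval rates are exposed
for inspection); a steadiness check flags the series `unsteady_flow` when the
coefficient of variation of interval rates exceeds 20%, which catches clot
rupture and reservoir depletion.  An initial wash can be excluded with
`start_offset`.

## Rheometry: plateau moduli and the flow limit

The clotting phase (small-amplitude oscillation, strain 0.015 at 1 Hz)
yields storage and loss moduli; the plateau is the mean over the final 20% of
the phase (configurable), and the loss tangent is the ratio of plateaus.  The
stress-ramp phase increases shear stress stepwise (default: 100 logarithmic
steps, 0.01–1000 Pa over 300 s) and the apparent viscosity
$\eta(t) = \tau / \dot\gamma$ falls abruptly when the gel yields.  The flow
limit is characterized by the maximal bearable strain $\gamma_{max}$ at the
last pre-transition point and the critical stress $\tau_0$ there.

* **"Abrupt fall" is quantified** as a drop of apparent viscosity below the
  running maximum divided by `fall_factor` (default 10).  A genuine gel-fluid
  transition spans orders of magnitude, so the detected point is insensitive
  to the exact factor — a property the tests assert directly.
* **`apparent_viscosity()` uses centered finite differences** (one-sided at
  the ends), the standard smooth-signal estimator.  **`flow_limit()` instead
  differentiates backwards internally**: a centered difference at the last
  pre-yield sample already contains the post-yield strain jump, which would
  drag the detected transition (and hence $\tau_0$) one ramp step early.
  Backward differences keep every pre-yield point uncontaminated, and the
  recovered $\tau_0$ lands within one ramp step of the programmed value
  across the tested grid.
* The generator's ramp strain is Hookean in the **secant modulus**
  $G_{ramp} = \tau^*/\gamma_{max}$ (with $\tau^*$ the last ramp stress at or
  below the programmed $\tau_0$), because measured fibrin gels bear more
  strain at yield than the small-strain plateau modulus alone would predict
  — the plateau $G'$ and the yield-point secant typically differ by a factor
  near 1.5.  Combinations where the two moduli disagree by more than a
  factor of 10 (configurable) are rejected as physically inconsistent.
  Post-yield flow is Newtonian with a programmed 1000-fold viscosity fall.

## Fiber morphometry

Fiber diameters are measured from grayscale micrograph-like images by a
classical pipeline, implemented in-package: optional Gaussian denoise, Otsu
global threshold, small-object removal, Zhang–Suen skeletonization, and an
exact Euclidean distance transform.  The local diameter at a skeleton point
is twice the distance-transform value times the pixel scale; 300 skeleton
points (the conventional per-clot sample size) are drawn uniformly at random
under a fixed seed.

* **Junction exclusion**: skeleton points within one local radius of a branch
  point are excluded — crossings are not fibers and would otherwise inflate
  the distribution.  Branch points are detected by the crossing number
  (three or more distinct neighbor runs), not the raw neighbor count, which
  would misflag staircase diagonals.
* **Border exclusion**: the frame is treated as background, and skeleton
  points within one local radius of the border are excluded, since clipped
  fibers under-read there.
* **Quartile convention**: quantile type 6 (the exclusive/Minitab rule), so
  `{90, 95, 100}` has Q1 = 90 and IQR = 10.  The convention is stated because
  both the "low-bottom quartile" and the IQR depend on it; both Q1 and IQR
  are reported.
* The generator renders **straight** anti-aliased fibers.  Curvature and
  branching change network topology but not the width ground truth, and
  straightness is what keeps the truth exact; consequently the recovery tests
  validate the diameter estimator, not segmentation of curved, bundled or
  densely branched networks.  The 2-D projection bias inherent to micrograph
  widths is accepted as-is, matching the measurement protocol.

## Distribution statistics

Diameter distributions are compared by Kuiper's statistic
$V = D^+ + D^-$ computed against a fitted family (lognormal by default —
standard for fiber diameters; gamma and normal are selectable and the
likelihoods are comparable).  Because the reference distribution is *fitted*,
textbook critical values are invalid; the p-value is calibrated by parametric
bootstrap: synthetic sample pairs of matching sizes are drawn from the pooled
fit and the identical fit-then-statistic procedure is re-run on each replicate
(`n_mc = 10000` by default).  The add-one estimator
$p = (1 + \#\{V_{mc} \ge V_{obs}\})/(n_{mc}+1)$ avoids $p = 0$ and is
deterministic given the seed.  Whether the reference is fitted to the other
sample or to the pool is exposed as `fit_target`, since both recipes are in
circulation; the default is `"other"`.

Two caveats govern the use of the Kuiper machinery on morphometry output.
First, measured diameters are pixel-quantized; a continuous family fitted to
heavily tied data will be rejected for the atoms themselves.  Second, and
more consequentially, skeleton-point samples are *clustered by fiber*: a
single fiber contributes many nearly identical diameters, which inflates the
empirical-distribution fluctuation far beyond the iid null that the
parametric bootstrap draws from, making the test anti-conservative on raw
skeleton samples even when two samples share a distribution.  Compare
conditions at the per-fiber or law level, or with the rank-based two-sample
KS test, when measurements are clustered; the type-I calibration that the
test suite verifies holds for iid samples, which is the regime the
bootstrap models.

All other comparisons use the two-sample Kolmogorov–Smirnov test: exact
p-values by lattice-path counting when the smaller group has at most 10
observations and the data are tie-free, the asymptotic Kolmogorov tail
otherwise.  The exact branch is verified against full enumeration of group
assignments in the tests.

## Clottability courses

Digestion of fibrinogen prolongs the clotting time of withdrawn samples;
readings strictly longer than 120 s are censored as non-clottable and
displayed as 121 s (a reading of exactly 120 s is still clottable).
Instrument "no clot detected" readings map to the same censored state.  The
time to non-clottability is the earliest censored digestion time on the
discrete withdrawal grid — no interpolation, because the withdrawal design
makes the grid authoritative.  The generator prolongs an initial 10 s
clotting time exponentially, so a larger programmed digestion rate always
loses clottability earlier — the monotonicity that underlies "protection"
comparisons between conditions.

## Reporting

`run_assay()` computes per-series metrics, converts them to relative units
(RU) against the mean of the reference condition, and summarizes each group
as mean (SD) in RU with two-sample KS comparisons against the reference;
`format_table()` renders `"1.53 (0.31)"`-style or `"95.1 [44.6]"`-style
cells (2 decimals for RU, 1 for nm, matching conventional printed precision),
marks KS $p < 0.05$ with a configurable symbol, and renders empty groups as
`"n.a."`.  Every table cell is traceable to rows of the accompanying detail
table, and identical configurations reproduce byte-identical CSVs.

## Known limitations

* The turbidity model is phenomenological (two logistic branches); it does
  not deconvolve polymerization or plasmin kinetics, and generator noise is
  white — drift, evaporation and edge effects are out of scope.
* Permeation stops at $K_s$; no capillary-model conversion to a literal pore
  radius is attempted.
* Rheometry covers a single-frequency oscillation followed by a stress ramp;
  frequency sweeps, large-amplitude harmonics and instrument inertia are out
  of scope.
* Morphometry measures apparent 2-D widths on straight-fiber renderings; no
  3-D reconstruction, branch-density or image-based pore-size estimation.
* The statistics module provides the machinery for significance calls on
  synthetic data; it does not reproduce any wet-lab measurement.
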