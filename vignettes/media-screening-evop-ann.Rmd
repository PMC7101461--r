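---
title: "EVOP factorial screening and surrogate optimization of fermentation media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EVOP factorial screening and surrogate optimization of fermentation media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evopann)
```

## The problem

Solid-state fermentation (SSF) yields of microbial enzymes depend strongly on
a handful of culture parameters — here the incubation temperature, the
initial medium pH, and the composition of the substrate mix (the wheat-bran
share, %WB, of a wheat bran + soybean meal bed).  Evolutionary operation
(EVOP) improves these parameters *in production*: instead of a large
one-shot design, each phase runs a small two-level factorial perturbation
around the current operating centre, repeated in cycles, and only moves the
centre when an effect demonstrably exceeds the experimental noise.  Once the
factorial signals die out, the accumulated observations can train a
response-surface surrogate — here both a quadratic polynomial and a small
feed-forward neural network — which is then optimized exhaustively over a
constrained grid to propose conditions beyond the tested lattice.

This package implements that whole loop for the three-variable case, with
the alkaline-protease screening campaign of *Rhizopus oryzae* on wheat
bran + soybean meal shipped as the worked example
(`protease_worksheet()`, `protease_training()`).

## The EVOP worksheet

One phase consists of ten runs: the centre duplicated (runs A1 and A6) and
the eight corners of the full $2^3$ factorial at
$\text{centre} \pm \text{half-step}$ per factor, in a fixed run order.
Coded levels are stored as integers $-1/0/+1$ so all contrasts are exact
integer arithmetic on the coding.  A *cycle* is one complete replicate of
the ten runs; cycle-to-cycle differences carry the noise information.

The substrate axis is represented as %WB throughout (centre 4:1 in grams
$\equiv$ 80 %, half-step 0.5 g $\equiv$ 10 %); `ratio_to_percent()` is the
documented bridge from mass-ratio notation.  This keeps the EVOP factor and
the surrogate input on one axis.

## Phase statistics

With responses $y_{A1},\dots,y_{A10}$ (one cycle, or per-run averages
across cycles):

* **Main effect** of a factor: $\bar y_{+} - \bar y_{-}$ over the four
  corners at its high and low coded level, i.e.
  $(\sum y_{+} - \sum y_{-})/4$; **interaction effects** use the sign
  product of two factors' codings.  Centre runs never enter a contrast.
* **Change-in-mean**: $\frac{1}{10}\sum_{i} y_i - \bar y_{\text{centre}}$.
  Strongly negative values mean the centre beats its whole neighbourhood.
* **Noise level** $s$: three estimators are exposed.  The classical range
  shortcut $s = f_{k,n}\,R_D$ (with the standard $f$ table for $k = 10$
  runs applied to the range $R_D$ of the per-run differences), the pooled
  paired estimate $\sqrt{\sum d_i^2 / 2k}$, and a `fixed` pass-through for
  reproducing an externally reported $s$.  With more than two cycles the
  data-driven estimators use the differences between the last two cycles;
  the classical sequential-update worksheet is deliberately not
  implemented, since every shipped analysis and the campaign simulator run
  two cycles per phase.
* **Error limits** at $n$ cycles: $2s/\sqrt n$ for run averages,
  $2s/\sqrt{2n}$ for effects, $1.78\,s/\sqrt{2n}$ for the change-in-mean.
  These divisors reproduce (at $n=2$, to within the source's own rounding)
  the limit table of the packaged campaign from its reported $s$ values;
  textbook EVOP variants differ in the third constant, and
  $1.78/\sqrt{2n}$ is the best fit among them.

The **decision rule** (`evop_decide()`) is: if any of the six effects
strictly exceeds the effects limit in magnitude, *shift* the centre one
half-step along each significant main effect (toward its sign); otherwise,
if the change-in-mean is more negative than its limit, the optimum has been
reached; otherwise run another cycle.  Strict inequality implements
"higher than the error limits"; an effect exactly at the limit is not a
signal.

Two reproducibility caveats about the packaged campaign are worth stating
plainly.  First, its recorded per-cycle $s$ values (100.65, 93.03) are not
recovered by any of the data-driven estimators from the recorded responses
(range and pooled both give $\approx$ 10–13); they are accepted via
`sd_method = "fixed"`, which is exactly what makes the recorded error
limits reproducible.  Second, the recorded main/interaction effects are not
reproducible from the recorded responses under the worksheet coding by any
standard contrast — the standard-contrast values (e.g. temperature
$+31.78$ on cycle I) are computed and tested instead, and the recorded
values are never asserted.  Both facts are respected rather than
reverse-fitted: the standard formulas are the only auditable definitions.

## The polynomial surrogate

`fit_quadratic_surface()` fits
$$\hat y = \beta_0 + \beta_1 T + \beta_2 \text{WB\%} + \beta_3\,\text{pH} + \beta_4\,\text{pH}^2$$
by ordinary least squares (`lm()` underneath; rank deficiency is an error
naming the collinear columns).  With $\beta_4 < 0$ the surface has the
interior stationary pH $-\beta_3/(2\beta_4)$ and pushes temperature and
%WB to the boundary of any box, which is why a lattice search is the
natural optimizer here.

`reference_surface()` carries the fixed reference coefficient set for the
packaged protease data.  It is deliberately distinct from a refit: the
reference coefficients are *not* an exact least-squares solution for the
packaged records (their residuals sum to $\approx 8.7$, not 0; whether a
weighted fit, a data subset or a transcription slip explains it is not
decidable from the data), so both surfaces are exposed and the refit is
tested only for properties a least-squares solution must have.

## The network surrogate

`mfnn()` trains a 3–10–1 fully connected feed-forward network — sigmoid
hidden layer, linear output — by Levenberg–Marquardt on min–max
normalized inputs and target (to $[-1, 1]$).  Choices that matter:

* **LM schedule**: initial damping $\lambda = 10^{-3}$, factor 10 down on
  an accepted step / up on a rejected one; stop on gradient
  $\infty$-norm $< 10^{-7}$, MSE $< 10^{-10}$, $\lambda > 10^{10}$ or 1000
  iterations.  These are the standard defaults for small dense problems.
  The Jacobian is computed by backpropagation and is tested against
  central finite differences.
* **Restarts**: weights start uniform in $[-0.5, 0.5]$; restart $r$ is
  seeded with `seed + r`, and the restart with the best overall $R^2$ on
  the full dataset wins, so the fit is a pure function of `(data, seed)`.
* **Split policy**: the default trains on all records — nine points cannot
  sustain a meaningful train/validation/test partition.  The optional
  `split = "holdout"` mimics a 7/1/1 protocol: one validation and one test
  record are set aside (seeded) and each restart early-stops after six
  consecutive validation-error increases, keeping the weights at the
  validation minimum.  A single held-out point cannot support an $R^2$ of
  its own, so held-out squared errors are reported instead.

**Known limitation.** With 51 free parameters and 9 training records the
default protocol interpolates the data (overall $R^2 = 1$ to numerical
precision) on essentially every restart.  An interpolant is faithful at the
lattice points it was trained on but unconstrained between them: its grid
maximum typically overshoots the largest measured activity and its argmax
location varies with the seed.  The holdout variant regularizes but is very
aggressive with one validation point.  Surrogate optima from so few records
should be read as *proposals for the next experiment*, not as predictions —
which is also how the screening campaign used them.

## The constrained grid

`grid_spec()` defaults to temperature 26–30 °C in steps of 1, %WB 70–90 in
steps of 2.5, and pH 4–8 in steps of 0.1 (41 × 5 × 9 = 1845 points), and
`enumerate_grid()` indexes it with pH varying slowest and %WB fastest:
$$\text{iteration} = i_{\text{pH}}\,(n_T\,n_{WB}) + i_T\,n_{WB} + i_{WB} + 1 .$$
The %WB and pH increments (2.5 and 0.1 rather than the coarser 5 and 0.2
sometimes quoted for this region) and this nesting order are the unique
reconstruction consistent with the packaged campaign's published
iteration-to-condition examples (e.g. iteration 1027 ↦ 30 °C, 70 %, pH
6.2); the total count is then 1845, and the package reports the true count
of whatever grid it enumerates.  Axis values are computed as
$\text{low} + i\cdot\text{step}$ with one final rounding to 10 decimals so
membership never drifts with floating-point accumulation.

`grid_optimize()` evaluates any surrogate with a `predict()` method at
every point, breaks argmax ties toward the lowest iteration, aborts on a
non-finite prediction naming the offending point, and reports the decade
block of iterations containing the argmax as the zoomed-in `window`.

## Synthetic data and campaigns

`true_surface()` defines a ground truth in the polynomial family above,
optionally plus interaction terms *in coded units* (they act on the sign
products of a generated worksheet, mirroring what a factorial can detect),
with three noise knobs: homoscedastic Gaussian `noise_sd` (default), a
multiplicative `noise_cv` alternative (cycle differences in real campaigns
scale roughly with response magnitude), and a shared per-cycle offset
`cycle_bias_sd` emulating batch drift.  Generated worksheet responses are
truncated at zero, as activities are; all shipped analyses operate far from
that floor.

What the generator emulates: a smooth low-order response surface, run-level
measurement noise, cycle-level bias, and the exact worksheet geometry.
What it does not: fermentation kinetics, substrate depletion, assay
nonlinearity, or any run-order/carry-over structure.  Passing tests
therefore validate the *statistics and the decision logic*, not the
biology: a real campaign can violate the smooth-surface assumption in ways
no test here probes.

`simulate_campaign()` closes the loop (worksheet → analysis → decision →
centre shift, phase by phase, child seed `seed + 1000·(phase−1)`), stopping
on `optimum_reached`, on a no-signal `continue_cycles`, or at the phase
cap, and reports the analytic box-constrained optimum of the surface for
comparison.  On a quadratic-in-pH surface with curvature and noise
comparable to the packaged campaign (peak ≈ 800 U/gds, $\sigma = 5$), a
campaign started two half-steps below the true optimum pH recovers it to
within one half-step in well over 90 % of seeds — this is exercised with
100 seeds in the test suite.

## Problem sizes used in the tests

The suite runs the full printed-arithmetic checks exactly; Monte-Carlo
properties use 100 seeds for campaign recovery and coefficient coverage,
20 seeds for the $1/\sqrt n$ error-shrinkage comparison (at $n = 20$ vs
200), 5 seeds × 64 restarts for network-fit quality, and 3 seeds × 64
restarts for the network grid-optimum comparison.  These sizes keep the
whole suite in the seconds-to-a-minute range while leaving the binomial
margins of the ≥ 90 % assertions comfortable.

## Interfaces

Everything is plain R: classed objects with `print`/`summary`/`coef`/
`predict`/`residuals`/`plot` methods, CSV readers/writers
(`read_worksheet()`, `read_dataset()`, comma/dot/UTF-8 with mandatory
header), and `run_pipeline()` chaining analysis → dataset assembly →
surrogate fit → grid optimization into one bundle that
`write_pipeline_json()` serializes with full-precision values, a 2-decimal
display block, and the input file's md5 digest.  Bundles deliberately embed
no timestamps so that identical inputs and seed reproduce byte-identical
output.
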