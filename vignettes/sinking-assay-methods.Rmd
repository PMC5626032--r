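---
title: "Methods: estimating phytoplankton sinking rates from plate-fluorometer kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating phytoplankton sinking rates from plate-fluorometer kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkassay)
```

## The measurement and its model

A microtitre well filled with an evenly resuspended phytoplankton culture is
read repeatedly from above by a plate fluorometer. Chlorophyll *a*
fluorescence emission is isotropic, and the received signal is weighted
towards cells near the top of the well (cells lower down receive less
excitation light and their emission is re-absorbed on the way up). As cells
sink away from the detector the relative fluorescence (RFU) declines,
until all cells rest at the bottom — a depth of 3.8 mm in both 96- and
24-well plates at the standard fill volumes — and the signal plateaus.

`sinkassay` converts such kinetic traces into sinking rates in
m d^-1^ through the following chain, applied per well by `run_assay()`:

1. **Scaling** (`scale_rfu()`). The trace is min–max scaled,
   $\mathrm{scaled}_t = (\mathrm{RFU}_t - \min \mathrm{RFU}) /
   (\max \mathrm{RFU} - \min \mathrm{RFU})$, so the even suspension reads 1
   and the settled plateau reads 0. This removes well-to-well differences
   in starting cell density. The bounds are the global minimum and maximum
   of the observed trace; when the minimum occurs before the last 10% of
   reads the trace has evidently not plateaued and downstream results carry
   a `min_early` flag.
2. **Inverse-square decay model.** With the signal weighted towards the top
   of the well, a homogeneous population sinking at a scaled rate $s$
   (per minute, in units of the culture depth) gives
   $\mathrm{scaled}_t = 1/(1 + t s)^2$ (`forward_scaled()`). This is a
   deliberately minimal model — no radiative transfer, no vertical
   concentration profile — and its adequacy rests on the weighting argument
   above, not on mechanism.
3. **Square-root linearization** (`depth_transform()`). Taking the square
   root gives $1/(1 + t s)$, which for $t s < 1$ expands as a geometric
   series to $1 - t s$ with remainder bounded by $(t s)^2$. Multiplying by
   the culture depth yields a *depth signal* in mm whose decline slope is
   directly in mm min^-1^ and whose intercept has the physical value of the
   culture depth. All regression happens on this depth signal.
4. **Segmented regression** (`fit_line()`, `fit_segmented()`). Many
   cultures show two sinking phases — a fast subpopulation (long chains,
   large or senescent cells) and a slow one. The depth signal is fitted
   both with a single line and with a continuous one-breakpoint
   piecewise-linear model whose segments meet at the breakpoint $\psi$.
5. **Model selection** (`select_model()`). The segmented model is retained
   only when the extra-parameters F-test (2 extra degrees of freedom: the
   second slope and the breakpoint) rejects the single line at
   $\alpha = 0.05$ *and* both fitted slopes are negative. An information
   criterion variant (BIC) is available.
6. **Rates and amplitudes** (`extract_rates()`, `amplitudes()`). Slopes in
   mm min^-1^ convert to m d^-1^ by the factor $1440/1000$. The first-phase
   amplitude is the fraction of the fitted depth signal at $t = 0$ lost
   before the breakpoint, $(y(0) - y(\psi))/y(0)$; the second phase takes
   the remainder, so the amplitudes always sum to 1 and estimate the
   relative abundances of the fast and slow subpopulations. The amplitude
   of a single-phase well is 1 by definition.

### The NPQ-relaxation rise

Cultures transferred from growth light into the dim assay environment can
*brighten* during the first ~30 min as non-photochemical quenching (NPQ)
relaxes, masking early sinking. `correct_npq_rise()` fits a segmented model
to the full trace; when the first segment rises significantly (one-sided
p < 0.05 on the first slope) and the second declines, the rise segment is
discarded, the sinking segment's line is extrapolated back to $t = 0$, and
the retained signal is rescaled multiplicatively so that the extrapolated
intercept equals the culture depth (i.e. scaled value 1). A trace that
rises and never declines is an error ("no sinking phase detected"), not a
silent pass-through.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `depth_mm` | 3.8 | mm | culture depth at standard fill volumes; both plate formats |
| `alpha` | 0.05 | — | conventional level for the segmented-vs-single F-test |
| `min_seg` | 3 | points | smallest segment leaving a residual degree of freedom |
| `intercept_mode` | `"free"` | — | see below |
| `npq_correction` | `"auto"` | — | correct only when a rise is statistically detectable |
| stationary `tol` | 0.05 | CV | "stable RFU" quantified as coefficient of variation below 5% over 3 days |

**Free vs fixed intercept.** An evenly resuspended well should start its
depth signal exactly at the culture depth, which argues for pinning the
intercept to `depth_mm`; noise and early-read artifacts argue for leaving
it free. Both variants are always computed and reported side by side
(`rate1_m_per_day` vs `rate1_alt_m_per_day`); the `intercept_mode` setting
only chooses which one is primary. The default is the free intercept, with
the fixed-intercept value as the companion column.

**Manual breakpoints.** `assay_config(breakpoints = list(A5 = 12.5))`
pins a well's breakpoint, skipping the search and the model selection — the
escape hatch for wells where the automatic breakpoint search fails but the
two-phase structure is evident from replicates.

## The breakpoint search and its numerical choices

The breakpoint is estimated by profiling: for a candidate $\psi$ the model
is conditionally linear, so its least-squares solution comes from a small
normal-equations solve. Candidates are the midpoints between consecutive
observed times that leave at least `min_seg` points per segment; because
the profiled RSS can dip anywhere between observations, every feasible
inter-observation interval is then refined by golden-section search and the
global minimum wins. Ties in RSS (within 1e-12) break towards the earliest
breakpoint. The procedure is deterministic and reproduces an exhaustive
dense-grid scan to within one grid step — the property the test suite
asserts against an independently coded brute-force oracle. Degenerate
inputs (fewer than `2 * min_seg` points, zero time variance, constant
traces) are rejected with specific errors rather than fitted.

Segments meet exactly at the breakpoint by construction (the hinge
parameterization $y = a + b_1 t + d\,(t-\psi)_+$), and adding the
breakpoint can never increase the RSS because the single line is nested in
the segmented model.

## Growth staging

Daily RFU series are staged with the modified Gompertz model on the log
scale, $y(t) = A \exp\!\big(-\exp(\mu e / A\,(\lambda - t) + 1)\big)$ with
$y = \ln(\mathrm{RFU}_t/\mathrm{RFU}_{\min})$, $A$ the asymptotic log
fold-increase, $\mu$ the maximum specific growth rate (the slope at the
inflection) and $\lambda$ the lag. Here $e$ is Euler's number — the
standard Zwietering formulation; descriptions of this model sometimes
mislabel $e$ as elapsed time, which cannot be, since $t$ already appears in
the exponent. The culture maximum is back-calculated as
$\mathrm{RFU}_{\max} = e^{A}\,\mathrm{RFU}_{\min}$. Fitting is nonlinear
least squares (Levenberg–Marquardt) with multi-start initialization ($A$
from the observed log range, $\mu$ from the steepest day-to-day log
difference, $\lambda$ from the last below-threshold day). By default
$\mathrm{RFU}_{\min}$ is the observed minimum of the series; since even the
first read sits slightly up the growth curve, that choice carries a small
(~1e-5 relative) bias on noiseless data, and a known inoculation baseline
can be supplied explicitly. A culture is flagged stationary on the first
day the trailing 3-day coefficient of variation drops to 5% or below.

## What the synthetic generator emulates — and what it does not

`simulate_trace()` generates
$$\mathrm{rfu}(t) = \Big[b + f_0 \sum_i w_i (1 + s_i t)^{-2}\Big]
\Big[1 - a_{\mathrm{npq}} e^{-t/\tau_{\mathrm{npq}}}\Big] + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma),$$
i.e. a one- or two-population mixture of the assay's own decay kernel, a
single-exponential multiplicative NPQ-relaxation recovery, an additive
baseline (settled cells at the well bottom still fluoresce), and Gaussian
detector noise applied after the NPQ factor. Defaults are the package's
reference study conditions: 40 reads over 200 min (5-min cadence),
subpopulation rates 0.05 and 0.005 min^-1^ at weights 0.3/0.7, baseline 5%
and noise 1% of the initial amplitude, no NPQ. A dilute single-population
condition (one population at 0.005 min^-1^, 3% noise over 180 min) stands
in for slowly sinking, low-signal cultures. `simulate_plate()` adds
per-well multiplicative lognormal jitter and emits a matching catalog.

Passing tests on these simulations show that the *pipeline* recovers the
structure its own model generates; they do not show that real traces follow
the inverse-square kernel, that real detector noise is Gaussian and
homoscedastic, or that NPQ relaxation is single-exponential. The generator
also reveals an honest limitation of the transform chain: a single
population observed before it has fully settled retains curvature after the
square-root and min–max rescaling, so at low noise the F-test resolves that
curvature and reports two phases. Single-phase classification of
single-population traces is therefore noise-dependent, and the test suite
asserts it as a dominant-fraction property across seeds rather than a
certainty. The mapping from a generative subpopulation weight to a fitted
amplitude is likewise only approximate under the transform; recovery is
asserted to ±0.15, and tighter claims are not made.

## Problem sizes used by the checks

The validation suite runs entirely on simulated data at desk scale: 50
random instances for the breakpoint oracle, 200 seeded null traces for the
type-I error of model selection (asserted to lie in [0.005, 0.105] around
the nominal 0.05 — breakpoint profiling inflates the F-test slightly, the
negative-slopes requirement deflates it), 20 seeds for the end-to-end
two-population and NPQ round-trip checks, and 100 noisy series for Gompertz
recovery. `scripts/acceptance.R` recomputes the same quantities from
scratch under a caller-supplied seed.

## Reproducing published per-well analyses

`read_supplementary_rdata()` converts `.RData` files of time-by-well trace
tables into the package's data model so that published per-well datasets
can be re-analysed with `run_assay()`. The reproduction tests in
`tests/testthat/test-acceptance.R` look for such files under
`tests/testthat/supplementary_data/` (or the directory named in option
`sinkassay.supplementary_dir`) and compare the recovered first/second-phase
rates and amplitudes against the published per-species values; they fail
with a pointed message when the files are absent.

## Known limitations

- The inverse-square model is heuristic; the depth variable in it is in
  units of the culture depth, and the linearization is only good for
  $t s \lesssim 0.5$. Strongly settled traces are curved, not piecewise
  linear.
- Only one breakpoint is supported; more than two sinking subpopulations
  fold into two phases.
- Regression is ordinary least squares; heteroscedastic noise (dilute
  cultures late in a trace) is not modelled.
- Whether published per-well standard errors derive from replicate spread
  or from the regression is ambiguous in general; the package reports both
  (regression SEs per well, replicate SEs per group).
- Stokes' law (`stokes_velocity()`) is provided as a reference for choosing
  simulation parameters and for order-of-magnitude sanity checks; it plays
  no role in rate estimation.
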