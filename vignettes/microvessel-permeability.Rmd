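---
title: "Quantifying vascular barrier function from microvessel leakage images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vascular barrier function from microvessel leakage images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselperm)
```

## The measurement

A microvessel-on-chip is a cylindrical channel (here radius
`r0 = 117.5` µm, half of a 235 µm casting needle) lined with endothelial
cells inside a collagen gel. Barrier function is read out by filling the
lumen with a fluorescent tracer and imaging its leak into the gel: three
axial positions per vessel, frames every 30 s for 5 min. The tighter the
junctions, the slower the extraluminal fluorescence grows.

This vignette documents the model behind the package's estimator, the
synthetic-data generator used to validate it, and the numerical and design
choices made where more than one defensible option existed.

## Transport model and its assumptions

The lumen is treated as an infinite source: the tracer reservoir is large
and the measurement short, so the lumen concentration `c0` is constant.
Outside the wall the tracer diffuses radially,

$$\frac{\partial c}{\partial t} = D\,\frac{1}{r}\frac{\partial}{\partial r}
  \left(r \frac{\partial c}{\partial r}\right), \qquad r_0 < r < R_{max},$$

with a membrane (Robin) condition at the wall,
$-D\,\partial c/\partial r|_{r_0} = P\,(c_0 - c(r_0,t))$, so the flux is
$J(t) = P\,(c_0 - c(r_0,t))$, and a far-field sink at $R_{max}$ that is kept
at least $6\sqrt{D\,T}$ beyond the wall so it is never reached (violations
are rejected). Transcellular uptake, advection/shear, and axial gradients
are all outside the model; leakage on the minute scale of this assay is
paracellular.

When $P r_0 / D \ll 1$ (the membrane-limited regime) the wall concentration
stays far below `c0`, $J \approx P c_0$, and the leaked mass per membrane
area $J\,t$ is linear in time — the regime the assay is designed around. At
the leaky end of the physiological range ($P \gtrsim 5\times10^{-7}$ m/s
with $D = 1.5\times10^{-10}$ m²/s, i.e. $P r_0/D \approx 0.4$–$0.8$) the
wall concentration builds up appreciably and the flux *declines* over the
record. A slope fit then underestimates `P` no matter how exact the
calibration; the early-window refits below mitigate but cannot remove this.
The test suite quantifies the consequence: recovery is within a few percent
in the membrane-limited regime, degrades to tens of percent at
$10^{-6}$ m/s, and stays strictly monotone in the true permeability — so
ordering and group comparisons survive even where absolute values compress.

## From images to permeability

### Calibration

The renderer and the estimator share one projection identity. A pixel at
transverse offset $x$ integrates the concentration along the optical axis
$z$; summing the whole frame therefore integrates the full extraluminal
mass per imaged length $L$, scaled by the gain. Because the lumen is an
infinite source, its projected contribution (the chord
$2\sqrt{r_0^2-x^2}\,c_0$) is constant in time, so

$$F_{out}(t_k) = \sum_{\text{frame}} I(t_k) - \sum_{\text{frame}} I(t_0)$$

isolates exactly the barrier-crossed tracer. This whole-frame difference is
deliberate: at early times most leaked tracer sits at $|x| < r_0$ — above
and below the cylinder — and a sum restricted to the segmented "outside"
region misses much of it, substantially underestimating the slope. The
baseline subtraction also removes
autofluorescence, detector offset and static PSF bleed.

The mean t = 0 intensity over the lumen disk is
$\bar I_0 = \gamma c_0 \frac{\pi}{2} r_0$ (mean chord of a disk), and the
leaked-mass growth rate is $2\pi r_0 J \gamma L / s^2$ counts/s, which gives

$$\hat P = \frac{s^2}{4\,L\,\bar I_0}\,\frac{dF_{out}}{dt}$$

with every optical factor cancelled. No absolute gain, concentration or
even the vessel radius enters the estimate.

### Geometry

The lumen is segmented on the first frame: Otsu threshold, hole fill,
largest connected component, plus a 3 px exclusion band around the mask
(kept as a partition contract and PSF buffer). Under projection
illumination the lumen's edge pixels are dim — the chord length vanishes at
the wall — so the thresholded mask systematically stops short of the true boundary. Two
quantities are therefore taken from
the background-subtracted transverse intensity profile $p(x)$ instead of
the raw mask, using the projected-disk identities
$\int p\,dx = \gamma c_0 \pi r_0^2$ and $p_{peak} = \gamma c_0\,2 r_0$:

* `r0_hat = 2 (∫p dx) / (π p_peak)` — the tests assert recovery within 2%
  on noiseless stacks, where the half-median-mask-width rule lands several
  percent low;
* `I_lumen0 = (π/4) p_peak`, the disk mean, preferred over the mask mean,
  which over-represents bright central columns and would bias `P_hat` low
  by a similar margin.

### Fitting windows, floor, aggregation

Ordinary least squares of the calibrated ordinate `y` on `t` with a free
intercept (absorbing any residual t = 0 offset). In vessel mode the full
record is fit first and the window is readjusted **once** (never
iterated): initial estimate > 8e-7 m/s → refit over [0, 60] s; between
1e-7 and 8e-7 → [0, 120] s; otherwise keep 0–5 min. The rationale is
saturation: a leaky vessel fills the field of view early and the late curve
flattens. Cell-free (hollow-channel) records sampled at ~1 s are fit over
[10, 30] s only, skipping the filling transient. Any window must contain at
least 3 samples.

A negative slope, or one whose 95% CI covers zero, is reported as
`floor_limited` with `P_hat` set to the detection floor
$t_{0.975,\,df}\times SE(\text{slope})$ — an upper bound defining the
smallest permeability distinguishable from zero at that noise level. The
index `BF = -log10(P)` (P in m/s) is only computed for positive values;
callers must apply the floor first.

Vessels are summarized as the arithmetic mean of their (up to three)
position estimates, with the index computed from the mean; a pooled fit of
the concatenated curves is the alternative we rejected because it weights
positions by their noise rather than equally. ΔBarrier subtracts the
batch-wise iso-osmotic mean index, making the reference group zero-mean by
construction and invariant to any uniform rescaling of `P`.

## The synthetic-data generator

The generator is the package's ground-truth instrument, emulating the
study conditions end to end: the forward solve above, then projection
imaging with chord + line-integral pixel values, Gaussian PSF blur, Poisson
shot noise, Gaussian read noise, and 16-bit quantization; cohorts draw
`log10(P) ~ Normal`, with condition shifts of +log10(2.69) (hypo-osmotic)
and −log10(7.44) (hyperosmotic) on the iso mean — the fold changes the
assay is designed to resolve.

Defaults, with units and why:

| parameter | default | rationale |
|---|---|---|
| `D` | 1.5e-10 m²/s | literature-typical for 4 kDa dextran in collagen |
| `r0`, `c0` | 117.5 µm, 1 a.u. | half the casting-needle diameter; gains cancel |
| `n_r`, `dt` | 300 cells, 0.1 s | solver grid; validated by mass balance, not tuned |
| `R_max` | `r0 + 8*sqrt(D*T)` | far-field margin above the 6-length precondition |
| pixel pitch | 2.5 µm | lumen ~94 px wide, typical 10x confocal sampling |
| FOV | 640 × 128 px | transverse half-width `r0 + 3*sqrt(D*T)` so the tracer cloud stays in frame over 5 min |
| gain | 1.28e8 counts/(a.u.·m) | lumen center ~30,000 of 65,535 counts |
| background | 1000 counts | detector offset > 3× read noise, so the zero clamp never censors the noise (censoring under-records small increments) |
| read noise | 300 counts | ~1% of lumen intensity |
| PSF sigma | 1 µm | sub-pixel widefield blur |
| frames | 11 × 30 s | the assay's 5 min protocol |

What the generator does **not** emulate: flow and shear stress, axial
inhomogeneity (all rows are statistically identical), stage drift and
registration error, photobleaching, transcellular uptake, and 3D confocal
sectioning. Passing recovery tests therefore demonstrate correctness of the
calibration and fitting logic under the stated physics — not robustness to
motion artifacts or focal-plane effects in real recordings. Whether the
original acquisition is a single slice or a projection is genuinely open;
we standardized on projection because it makes the intensity–mass
proportionality exact and self-consistent within the package.

## Numerical choices

* **Solver**: conservative finite-volume discretization, Crank–Nicolson
  stepping (unconditionally stable, second order in space), with the wall
  concentration extrapolated through the Robin condition
  (`P_eff = P / (1 + P Δr / 2D)`). The time-invariant propagator is
  factored once per solve. Discrete cumulative influx and stored mass agree
  by construction; every solve asserts the balance to 1e-3 and is
  cross-checked in the tests against an independent explicit-Euler solve on
  a 4× finer grid.
* **Renderer quadrature**: the per-column line integral is a sparse weight
  matrix over radial nodes (half the min of pixel pitch and radial step per
  z-cell, partial-cell overlap weights), so rendering many noise
  realizations of one vessel is a matrix product. Noiseless conservation is
  tested to 2%.
* **Degenerate inputs**: constant frames, components touching both
  transverse borders, sub-5%-area components, empty masks, constant
  expression rows, and non-positive band signals are all explicit errors
  rather than silent numbers; saturation (>1% of lumen pixels at full
  scale, or >5% of any frame) is flagged and propagated.

## Colocalization and morphometry choices

Colocalization is mask-based (fractions of overlapping positive pixels),
not intensity-correlation (Pearson/Manders): the downstream readouts are
"fraction of A-positive pixels inside B". Otsu is the default threshold and
every applied threshold is recorded in the result, since the original
processing chain's exact thresholds are not public. The denominator is
always channel A (the protein of interest). Quantile thresholding is
provided for monotone-invariance; channels are assumed registered.

Shape metrics use pixel-count areas, moment-matched ellipse axes
(aspect ratio from the square root of the eigenvalue ratio of the second
central moments), and a four-direction Cauchy–Crofton perimeter. The
perimeter choice is deliberate: chain-code boundary lengths overestimate
digital circles by ~8%, which would push disk circularity to ~0.86; Crofton
keeps disks within 1%. The cost is a known corner bias — the directional
quadrature underestimates the perimeter of an axis-aligned square by ~5%,
so square circularity reads ≈0.88 rather than the continuum π/4 ≈ 0.785.
For roundish cells (the use case) the Crofton behavior is the right
trade-off; the square response is asserted against its closed form in the
tests, and circularity may slightly exceed 1 for small disks (values are
meaningful up to ~1.1). Border-touching cells are flagged and excluded from
summaries by default, since truncated outlines bias all four metrics. The
mean 3D cell area divides the imaged half-surface `π r h` by the nuclei
count.

Plate-assay formulas use the sample (n−1) standard deviation for row
z-scores — chosen so the canonical `{1,2,3} → {−1,0,1}` identity holds —
and default the background to 0 when not supplied.

## Problem sizes used in validation

The shipped tests run the full pipeline at 4 true permeabilities × 10
imaging seeds (plus 10 zero-permeability controls and 10 narrow-FOV
window-benefit comparisons), sharing one transport solve and one projection
weight matrix per condition; fixtures are a 10,000-pixel colocalization
target and ~100 px shape primitives. These sizes were chosen to estimate
medians and flag rates stably while keeping a complete run in tens of
seconds; the generator scales to larger cohorts through
`simulate_cohort()` and `run_demo()`.

## Known limitations

* Absolute accuracy degrades above ~5e-7 m/s for the physical reason given
  earlier; ranking and ΔBarrier comparisons remain valid (monotonicity is
  tested per seed).
* The detection floor depends on the fitted window's residual noise; it is
  an upper bound, not an estimate.
* Segmentation assumes one vessel, axis along image rows, brighter than
  background at t = 0 with contrast ratio ≥ 2.
* No drift/registration correction; frames are assumed aligned.
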