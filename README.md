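# vesselperm

Quantitative barrier-function analysis for 3D microvessel-on-chip leakage
assays, in R.

Engineered microvessels — endothelial cells lining a cylindrical channel in a
collagen gel — are the standard in vitro platform for studying vascular
barrier integrity. The routine readout is a time-lapse recording of a
fluorescent tracer (e.g. 4 kDa FITC-dextran) leaking from the vessel lumen
into the surrounding matrix. `vesselperm` turns such recordings into an
apparent permeability coefficient and a barrier-function index, and bundles
the companion computations used alongside that assay: colocalized-pixel
fractions for junction/nuclear-localization imaging, per-cell morphometry on
label masks, and plate-assay normalizations (transwell permeation %, WST-1
viability %, heatmap z-scores, western-blot fold changes). A physics-based
synthetic-data generator with exact ground truth makes every stage testable
without microscopy data.

## The estimator

Tracer transport across the endothelial barrier is modelled as radial
diffusion from a cylindrical lumen of radius `r0` held at constant
concentration `c0` (infinite source), through a semipermeable membrane with
permeability `P` (m/s):

    dc/dt = D (1/r) d/dr (r dc/dr),    r0 < r,
    -D dc/dr |_{r0} = P (c0 - c(r0, t)),    J(t) = P (c0 - c(r0, t)).

In the membrane-limited regime (`P r0 / D << 1`) the flux is constant,
`J = P c0`, and the cumulative leaked mass per membrane area `J*t` grows
linearly in time. In a projection image the integrated extraluminal
intensity is proportional to that leaked mass, and all optical gains cancel
against the t = 0 lumen intensity, giving the calibrated estimator

    P_hat = s^2 * (dF_out/dt) / (4 * L * I_lumen0),

with `s` the pixel pitch, `F_out(t)` the baseline-subtracted whole-frame
intensity sum, `L` the imaged vessel length, and `I_lumen0` the mean t = 0
intensity over the lumen disk (mean chord of a disk = (pi/2) r0 — hence the
factor 4). Fast leakage saturates the field of view, so the fitting window
is readjusted once, following the assay's standard thresholds: estimates
above 8e-7 m/s are refit over the first 60 s, estimates in 1–8e-7 m/s over
the first 120 s, and slower vessels keep the full 5 min record. Slopes
indistinguishable from zero are reported at the detection floor and flagged.

Barrier tightness is summarized as the barrier-function index

    BF = -log10(P),    Delta-Barrier_i = BF_i - mean(BF of iso-osmotic controls in the same batch),

so a tenfold drop in permeability is exactly +1 index unit.

## Worked example

Simulate one vessel at a known permeability and re-estimate it:

```r
library(vesselperm)
sim <- simulate_leakage_stack(P_true = 1e-7, seed = 1)
sim$stack
#> Image stack: 11 frames of 128 x 640 px (2.50 um/px), t = 0..300 s

fit <- estimate_permeability(sim$stack)
fit
#> Permeability fit (vessel mode)
#>   P = 9.37e-08 m/s, barrier function = 7.03
#>   window [0, 300] s, R^2 = 0.9999, n = 11
```

The estimate is within 7% of the simulated truth; the fit kept the full
0–300 s window because the vessel is slower than 1e-7 m/s. `summary(fit)`
adds the slope confidence interval and the detection floor; `plot(fit)`
shows the calibrated leakage curve with the fitted line and window.
Geometry is recovered alongside:

```r
attr(fit, "geometry")
#> Lumen geometry: r0_hat = 118.6 um, L_hat = 320 um, 10919 mask px (+3 px buffer)
```

(the true lumen radius is 117.5 um). Cohorts with log-normal
vessel-to-vessel spread and osmotic condition shifts come from
`simulate_cohort()`; `aggregate_vessel()` averages up to three imaging
positions per vessel, and `delta_barrier()` references each vessel to its
batch's iso-osmotic mean. `run_demo()` chains all of this end to end and
writes per-position and per-vessel CSV tables plus a JSON run log, and
`inst/cli/vesselperm.R` exposes the same steps as shell subcommands
(`simulate`, `permeability`, `coloc`, `morph`, `assay`, `demo`).

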