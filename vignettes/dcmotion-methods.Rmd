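---
title: "Models and estimators behind dcmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind dcmotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmotion)
```

`dcmotion` quantifies dendritic-cell 3D-migration experiments: track
kinematics, chemotaxis directionality, front–rear polarity from images,
nanoscale clustering from localization microscopy, and population
migration indices. This vignette documents the models, the estimator
choices where more than one convention exists, the defaults with their
units, and what the synthetic generators do and do not emulate.

## Units and coordinate conventions

Tracks live in y-up Cartesian micrometre coordinates with time in
minutes. Images are row-major rasters with the origin at the top left and
the row index increasing downward; pixel `(r, c)` has its centre at
`((c - 0.5) px, (r - 0.5) px)` micrometres. Localization patterns use
nanometres. No function converts between these frames implicitly; the
import functions (`read_tracks()`, `read_cell_image()`,
`read_localizations()`) are where calibration enters, and calibration is
always a required user input because pixel sizes are
microscope-specific.

## The persistent random walk generator

No standard motility model is implied by manual tracking data itself, so
the synthetic track generator uses the classical amoeboid null: a
fixed-speed persistent random walk. The heading angle performs a
wrapped-Gaussian walk with per-step standard deviation
`sqrt(2 dt / P)`, giving directional correlations that decay over the
persistence time `P`; the two-dimensional motility coefficient
`D = s^2 P / 2` is exposed on the parameter object. Gradient bias `b` in
`[0, 1]` steers each step along `normalize((1 - b) u + b g)` at speed
`s`, where `u` is the persistent heading and `g` the unit gradient. This
convex-combination rule was chosen over adding a drift vector to the
displacement because it makes both limits exact: `b = 0` is an isotropic
PRW whose displacement angles to the gradient axis are uniform on
`[0°, 180°]` (mean 90°), and `b = 1` moves every cell straight up the
gradient (angle exactly 0°); in between the mean angle decreases
strictly with `b`, and the mean drift is approximately `b s dt` per step
for small `b`. Defaults (`speed` 4 µm/min, `dt` 4 min, `persistence`
2 min) sit at the scale of mature DCs in collagen imaged every few
minutes.

The generator emulates the statistical structure the track analyses
assume — independent cells, stationary speed, planar isotropy — and
deliberately not the features of real 3D data it has no ground truth
for: z-projection artefacts, collagen heterogeneity, cell–cell
collisions, speed fluctuation within a track, or tracking errors.
Passing recovery tests therefore shows the estimators are correct, not
that real data satisfy their assumptions.

## Track statistics

*Velocity* is total path length over elapsed time, per track.

*MSD* is computed per cell over all overlapping start points at each lag
(the standard sliding-interval estimator), and the group curve is the
unweighted mean over the cells whose track supports at least one
interval of that lag — cells tracked for different lengths contribute
only where they have data, and the per-lag cell count and SEM are
reported alongside. The alternative of weighting cells by their number
of intervals is exposed (`weight = "intervals"`) but is not the default,
because per-cell-then-average matches the convention of averaging each
cell's MSD curve. Oracles: ballistic tracks give `MSD = (s τ)^2`
exactly; uncorrelated-step walks give `MSD = 4 D τ` with
`D = s^2 dt / 4`.

*Euclidean displacement* takes the first sample at or after the horizon
(default 60 min of tracking) rather than interpolating between frames —
interpolation would invent positions. Tracks shorter than the horizon
are excluded and counted. No burn-in trimming is applied to track
starts; if an adaptation period should be excluded, trim before import.

## Chemotaxis statistics

The gradient frame is fixed by two points on the chemokine-region border
plus (optionally) a point on the source side; tracks are rigidly rotated
and shifted so the border lies on the x axis and the gradient along +y.
The per-cell statistic is the angle of the overall displacement vector
to the +y axis, in `[0°, 180°]`. Angles are averaged arithmetically, not
circularly: the statistic is an unsigned deviation from the gradient
axis, for which 90° is the no-directionality reference, and a circular
mean would be the wrong summary. Cells with zero net displacement have
no direction and are excluded with a warning rather than assigned 90°,
so they cannot dilute the group mean.

Group comparison uses the percentile bootstrap of the difference in
group means: resample cells with replacement within each group (sizes
preserved), `B = 10,000` by default, CI from the empirical quantiles.
Percentile rather than BCa was chosen for transparency and because the
statistic is a smooth mean difference on a bounded scale; the seed is a
mandatory argument. Resampling is flat over cells; donors are not
resampled hierarchically (per-donor means are reported alongside for a
donor-level reading). Calibration: under the null the 95% CI contains 0
in 95% ± 2.5 pp of 500 simulated replications (checked in the test
suite and recomputed by `scripts/acceptance.R`).

## Polarity imaging

Segmentation is a global threshold (Otsu by default, configurable to a
fixed value) on the chosen channel, keeping the largest connected
component and filling holes. Background pixels are invalid, not zero:
they enter no mean, so enlarging the canvas changes no measurement. Area
ties between components are broken toward the smaller centroid row and
logged.

The polarity axis is the principal axis of the cell mask translated to
pass through the nucleus centroid. Marching along the axis in
quarter-pixel steps finds the nucleus-edge and cell-edge crossings on
both sides; the side with the shorter nucleus-edge-to-cell-edge distance
is the rear. A symmetric cell is a tie; it is resolved deterministically
to the negative axis direction and flagged, never silently.

The rear/front ratio partitions cell pixels by the line through the
nucleus centroid perpendicular to the axis and reports the ratio of
regional mean intensities. Regional means were preferred to point reads
from a smoothed surface plot because they are objective, and they
preserve the quantity being measured (rear-over-front intensity
enrichment relative to the nucleus). The width-averaged profile projects
cell pixels onto the axis, bins at one pixel size from the rear-most (or
front-most) point, averages each bin over the full cell width, and
normalizes to the per-cell maximum; group profiles average the per-cell
normalized curves per offset (not the other way around). The default
length of 25 µm covers the rear or front half of a typical elongated DC;
the sampling step equals the image's own pixel size rather than a fixed
220-sample grid, which corresponds to one specific calibration.

The synthetic polarized cell is an ellipse with a piecewise-constant
marker (bright rear half split at the nucleus centroid, ratio
`rear_front_ratio`, default 2), Gaussian noise inside the cell (default
5% of the base intensity), and exact ground truth channels. It emulates
the intensity contrast and geometry the pipeline measures, not the
texture of actin networks, partial-volume edges, or uneven illumination.

## Nanoscale clustering

The pair correlation function is estimated with annulus binning and
translational edge correction (each ordered pair at displacement
`(dx, dy)` in an `Lx × Ly` window weighs
`Lx Ly / ((Lx - |dx|)(Ly - |dy|))`), normalized by
`n (n - 1) / |W|` pairs per unit area; `edge_correction = "none"` is
available for comparison. `r_max` must stay below half the shorter
window side. Defaults `r_max` 200 nm, `dr` 10 nm suit membrane-protein
clusters imaged at dSTORM densities.

The cluster model fitted to g(r) is the Thomas-process form
`g(r) = baseline + A exp(-r^2 / (4 σ^2))`, by weighted least squares
(weights = per-bin pair counts, Levenberg–Marquardt). The reported
**cluster diameter is defined as 4σ̂** — twice the 2σ radius, enclosing
about 95% of a Gaussian cluster's mass. This is a reporting convention
of this package; absolute diameters are comparable across groups
analyzed with the same convention but not directly against pipelines
that define diameter differently. Fits with σ̂ pinned at the search
bounds are flagged non-converged and excluded from group summaries (no
value is fabricated); fits whose amplitude is within two standard errors
of zero are flagged unclustered. Localization-uncertainty deconvolution
and multi-blinking correction are not applied — a stated limitation:
repeated blinking of one fluorophore inflates short-range g(r) in real
dSTORM data and can bias σ̂ downward there.

The Thomas generator (defaults `kappa` 2×10⁻⁶ parents/nm², `mu` 80,
`sigma` 30 nm, 5,000 × 5,000 nm window ≈ 4,000 points) draws parents in
the window dilated by 4σ so the retained pattern is a piece of the
stationary process with expected count `kappa mu |W|`. Its closed-form
`g(r) = 1 + exp(-r^2/(4σ^2)) / (4π kappa σ^2)` (`thomas_pcf()`) is the
oracle for the estimator and the fit: recovery simulations at these
densities show under 1% median bias in σ̂.

## Population indices

Percent migration, per-donor relative migration (normalized within donor
before averaging — pooled normalization is a different estimand and is
deliberately not offered), and the homing index
`HI = (%FR_t/%V_t)/(%FR_i/%V_i)`. `HI` satisfies two exact identities
used as tests: dye-swap reciprocity `HI(a,b,c,d)·HI(b,a,d,c) = 1` and
invariance to rescaling tissue (or input) percentages by a common
factor. Inconsistent counts (`n_migrated > n_input`) and zero
denominators are errors, not silently propagated values.

## Reproducibility and numerical choices

All stochastic functions take an integer seed and restore the caller's
RNG state; per-replicate substreams derive from one master seed
(`split_seed`), so per-cell streams are independent yet reproducible,
and a fixed seed yields bit-identical outputs. Degenerate inputs are
handled explicitly: zero-displacement tracks excluded, empty
segmentation masks and empty rear/front partitions are classed errors,
the measure-zero heading-exactly-opposite-gradient case falls back to
the gradient direction, and rear/front ties are flagged. Validation
errors carry classes (`dcmotion_parameter_error`, `dcmotion_data_error`,
`dcmotion_format_error`, ...) so pipelines can react programmatically.

Problem sizes used in the packaged checks — 10,000 tracks for the null
angle, 1,000 tracks for the Brownian MSD slope, 500 replications ×
B = 2,000 for bootstrap coverage, 50 paired Thomas simulations of
~4,000 points, 20 polarized-cell seeds — were chosen so each statistic's
Monte-Carlo error sits well inside the property band being checked.

## Known limitations

- Tracks and images are planar; z-resolved quantities are out of scope.
- The PRW is a stand-in motility model, not a fitted description of DC
  motion; persistence-time fitting is intentionally not provided.
- Cluster diameters depend on the 4σ convention and ignore localization
  noise (above).
- The nucleus-free rear proxy sometimes used for time-lapse data (the
  widest point of the cell) is not implemented; polarity geometry
  requires a stained nucleus channel.
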