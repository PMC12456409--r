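# dcmotion

Quantitative readouts for dendritic-cell (DC) 3D-migration experiments, in
one tested R package. Amoeboid leukocytes such as DCs migrate through
collagen by actomyosin-driven shape change; experiments on this biology
produce four very different kinds of raw data, and `dcmotion` covers the
analysis of each:

- **Track kinematics** — time-lapse cell tracks (manual-tracking CSV
  exports) are summarized as mean velocity (path length / elapsed time),
  mean squared displacement MSD(τ) = ⟨|r(t+τ) − r(t)|²⟩ averaged per cell
  over overlapping intervals and then across the cells that support each
  lag, and the Euclidean distance |r(t*) − r(0)| reached after a fixed
  tracking horizon (default 60 min).
- **Chemotaxis directionality** — tracks are rotated/shifted so the
  chemokine-region border lies on the x axis and the gradient along +y;
  each cell's overall displacement angle θ = arccos(d·ŷ/|d|) ∈ [0°, 180°]
  is read against the gradient (0° = straight up the gradient; an average
  of 90° = no directionality). Two groups are compared by the percentile
  bootstrap of the difference in mean angle with a 95% CI.
- **Front–rear polarity** — from multi-channel images: Otsu segmentation
  with hole filling, a polarity axis anchored on the nucleus (the rear is
  always the side with the shorter nucleus-to-edge distance), rear/front
  mean-intensity ratios split at the nucleus centroid, width-averaged
  axial line profiles normalized to each cell's maximum, and foci counting
  per unit cell area.
- **Nanoscale clustering** — per-cell single-molecule localization
  patterns are reduced to the pair correlation function g(r) with
  translational edge correction and fitted with the Gaussian cluster model
  g(r) = baseline + A·exp(−r²/4σ²) (the Thomas-process form); the reported
  cluster diameter is 4σ̂.
- **Population indices** — transwell percent migration
  (100·n_migrated/n_input), per-donor relative migration, and the in vivo
  homing index HI = (%FR_tissue/%V_tissue)/(%FR_input/%V_input) for
  co-injected dye-labelled populations.

A synthetic-data module generates ground-truth inputs for every stage:
persistent-random-walk tracks with tunable gradient bias, elliptical
polarized cells with an off-center nucleus and a known rear:front ratio,
Thomas-process clustered point patterns, and binomial migration counts.
Every analysis is validated against these generators or against closed
forms (Brownian MSD = 4Dτ, the Thomas g(r), exact index algebra).

## Worked example

```r
library(dcmotion)

# unbiased vs gradient-biased synthetic cells
wt <- generate_prw_tracks(prw_params(n_tracks = 50, n_steps = 20,
                                     dt = 4, speed = 4, bias = 0.3, seed = 1))
kd <- generate_prw_tracks(prw_params(n_tracks = 50, n_steps = 20,
                                     dt = 4, speed = 2.4, bias = 0.3, seed = 2))

mean(mean_track_velocity(wt))   # 4.0 um/min (fixed step length)
mean(mean_track_velocity(kd))   # 2.4 um/min

msd_curve(wt, max_lag = 20)[1:3, ]
#   lag_min      msd          sem n_cells
# 1       0   0.0000 0.000000e+00      50
# 2       4 256.0000 3.348163e-15      50
# 3       8 593.6468 1.055203e+01      50

euclidean_displacement(kd, horizon = 60, relative_to = wt)
# <displacement_summary> horizon 60 min: 50 tracks, mean 43.96 +/- 3.11 um, relative 0.580

bt <- bootstrap_angle_difference(displacement_angles(wt),
                                 displacement_angles(kd),
                                 B = 10000, seed = 7)
bt
# <angle_bootstrap> diff = -3.22 deg, 95% CI [-16.17, 9.60] (B = 10000)
#   CI contains 0
```

The two groups share the same chemotactic bias but differ in speed, and
the bootstrap correctly finds no directionality difference (CI straddles
0) — speed and chemotaxis are decoupled readouts.

Polarity and clustering run the same way from their generators:

```r
img  <- generate_polarized_cell_image(polarized_cell_spec(seed = 1))
mask <- segment_cell(img, "signal")
geom <- compute_geometry(mask, img$channels$nucleus > 0.5, img$pixel_size)
rear_front_ratio(img, geom)      # 2.0006 (truth: 2.0)
geom$rear_distance               # 8 um; always <= front_distance

pat <- generate_thomas_pattern(thomas_params(sigma = 30, seed = 1))
fit_cluster_model(pair_correlation(pat, r_max = 200, dr = 10))
# <cluster_fit> sigma = 30.2 nm, diameter = 120.9 nm, A = 45.55
```

A command-line interface wrapping the same functions is installed at
`system.file("cli", "dcmotion.R", package = "dcmotion")` with subcommands
`simulate-tracks`, `track-stats`, `chemotaxis`, `clusters`, `counts` and
`polarity`; every run writes a manifest recording parameters, seed and
package version.

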