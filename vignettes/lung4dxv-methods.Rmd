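---
title: "Models and methods behind lung4dxv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lung4dxv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lung4dxv)
```

This vignette explains the models implemented by `lung4dxv`, the
assumptions behind them, the tunable parameters that matter, and the
choices made where the design was genuinely open. It states no empirical
result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## Coordinate and unit conventions

Volumes are arrays with `dim = c(nz, ny, nx)` — axis order (z, y, x),
z being the long (cranio-caudal) axis and the rotation axis of the
scanner model. Voxel indices in all tables are 0-based; world lengths are
voxels × `voxel_size`. Times are milliseconds within one breath, with
t = 0 at end-expiration (functional residual capacity, the zero reference
of every volume series). Volumes of air are reported in `voxel_size`³
units.

## The synthetic breathing lung

The phantom exists so that every downstream stage can be validated
against closed-form ground truth. It is generated, not stored: identical
`phantom_spec()`s (including `seed`) give bit-identical datasets.

**Anatomy.** The lung is a generic ellipsoid (semi-axes 0.42 of each grid
dimension) — deliberately not anatomically faithful; it provides an
interior, a boundary and a volume, which is what the measurement chain
needs. Inside it grows a full binary airway tree: segment lengths and
radii decay geometrically (ratios 0.78 and 0.75 per generation; trachea
radius 5% of the grid edge), branch half-angles of about 33° carry seeded
jitter, and the branching plane rolls by ~90° between generations so the
tree fills space. A tree of *g* generations has 2^(g+1)−1 segments and
2^g terminals; the default *g* = 6 matches the deepest generation the
imaging chain is meant to resolve. Trees that leave the grid raise an
error naming the first offending segment.

**Appearance.** Phase-contrast imaging of alveolar tissue produces a
speckle texture; the phantom renders it as band-limited Gaussian noise
with autocorrelation FWHM equal to `speckle_grain` (default 5 voxels),
passed through `tanh` so the parenchyma — a tissue/air mixture — never
becomes as dark as a pure-air lumen. Airway lumens are rasterised as dark
capsules along the centerlines; tissue outside the lung envelope is a
featureless mid-grey. Speckle is a texture model only: no wave-optics
propagation is simulated, so tests exercised on the phantom say nothing
about phase-retrieval physics, only about geometry, motion and
measurement.

**Motion.** The displacement field is radial about the lung centre:

u(x, t) = a · g(ρ) · (x − c) · S(x, t),

where ρ is the ellipsoid-normalised radius, g(ρ) = 1 − k·ρ²/2 is a
centre-weighted taper (default `center_taper` k = 0.4, so the middle of
the lung expands most, as healthy lungs do), and a = `tidal_fraction`/3
sets the peak volumetric strain (default 0.2). The divergence is then
available in closed form, div u = a(3 − (5k/2)ρ²)·S plus defect terms.
The temporal factor rises as a raised cosine over the inspiratory time
and decays as exp(−(t − t_insp)/τ) over expiration, making the
expiratory time constant a direct phantom parameter (default `base_tau`
80 ms, a realistic small-animal scale). Defaults for the ventilation
protocol are PIP 12 / PEEP 2 cm H₂O, 250/250 ms inspiration/expiration,
120 breaths/min, 30 frames/s; the pressures are metadata only — no
pressure–volume mechanics is modelled.

**Defects.** A `defect_spec()` is a sphere inside which expansion is
scaled by `expansion_scale` ≤ 1 and τ by `tau_scale` ≥ 1. Two supports
are available. `"sphere"` (default) applies an analytic smoothstep weight
over a 3-voxel edge: the field stays smooth and the divergence is fully
closed-form. `"regions"` extends the defect to the whole territory of
every terminal airway whose endpoint lies in the sphere, with a *sharp*
weight: each ventilation unit then carries exactly one time constant —
the right study condition for per-region τ recovery — at the cost of a
strain discontinuity across territory boundaries (patchy disease does
produce strain gradients there, though not true tears; the surface sheet
term is omitted from the divergence, which is the one-sided closed form
inside each territory). With a smooth weight, boundary territories would
inherit mixed decay and no clean two-group condition would exist.

**Warping.** Each phase is the reference volume pulled back through the
negated forward field (valid to second order at these strains), sampled
with Keys tricubic interpolation. Trilinear sampling (`order = 1`) is
available but not the default: its fraction-dependent triangular filter
measurably distorts the texture used for subvoxel velocimetry
validation.

**Ground truth.** Per-terminal air-volume series are voxel sums of the
closed-form divergence over the generator's own nearest-endpoint
partition of the parenchyma; summed over terminals they equal the
whole-lung series identically, which is what the conservation tests
assert.

## Gated reconstruction

`gating_schedule()` encodes the ventilator trigger: `frame_rate × 60 /
respiratory_rate` must be a whole number of time bins or gating would
drift across breaths (an error, not a warning). Binning is a partition:
every projection lands in exactly one phase bin and empty bins are
reported by index. The projector computes cone-beam line integrals by
ray sampling at half-voxel steps; the FDK reconstructor pre-weights by
the cosine of the cone angle, ramp-filters detector rows in the
frequency domain (Kak–Slaney discrete kernel, zero-padded to the next
power of two), and backprojects with inverse-square distance weighting.
Projections need not be uniformly spaced: each is weighted by its
angular gap, matching interleaved gated acquisitions where each phase
sees a different subset of angles. The reconstruction grid is a cube at
the isocenter with voxel equal to the effective pixel size
`detector_pitch × r1 / r2`; with the default geometry (0.36 m / 3.0 m,
194 µm pitch) that is 23.3 µm. Geometric calibration is out of scope —
geometry is supplied as known, which for the phantom it is, exactly.

## Airway segmentation

The tubularity filter computes the scale-normalised Gaussian Hessian
(γ = 2) at geometrically spaced scales (default ten scales spanning
1–30 voxels), takes eigenvalues |λ1| ≤ |λ2| ≤ |λ3| per voxel, and forms
the classic three-factor vesselness with α = β = 0.5 and the
structureness cutoff set per scale to half the maximum Hessian norm —
the original conventions, exposed in `vesselness_params()`. Airways are
*dark* tubes, so the response requires λ2, λ3 > 0; segmentation runs on
the first (end-expiration) phase, where distal gas volume is minimal and
airway contrast maximal. Flood fill takes the 26-connected component of
the thresholded response containing the tracheal seed; the default
threshold is Otsu's threshold of the positive response histogram, a
stand-in for the interactive thresholding used with commercial tools.

Skeletonization uses sequential topology-preserving thinning: foreground
voxels are visited in increasing distance-transform order and removed
when they are simple points (one 26-connected foreground component in
the punctured neighbourhood, one 6-connected background component in the
18-neighbourhood) and not curve endpoints. The skeleton becomes a voxel
graph, split into segments at bifurcations; terminal spurs shorter than
`prune_factor` (default 2) times the local radius are pruned, chains
re-merged, and any non-binary junction cascaded into binary ones.
Generations count bifurcations from the root. Radii come from the exact
Euclidean distance transform of the mask. On rendered phantoms the chain
recovers a generation-3 tree exactly at the default prune factor; deeper
trees whose distal segment lengths approach the junction blob size need
a slightly larger prune factor (the generation-4 check in the test suite
uses 3). Resolving the default generation-6 tree from images is beyond
the desk-scale phantom (distal radii fall below one voxel) and is not
claimed.

## Velocimetry

Pre-processing is Gaussian smoothing (σ = 1) followed by a radial
raised-cosine band-pass (defaults 0.01–0.25 cycles/voxel, retaining most
of the speckle power while removing DC and high-frequency noise). When a
lung mask is supplied, everything outside it — chest wall, airway
lumens — is flattened to the parenchymal mean first, so strong
anatomical edges cannot leak through the filter into windows near the
lung boundary.

Interrogation windows are 32³ voxels with 50% overlap (the grid spacing
is therefore 16 voxels). Each window pair is correlated in the frequency
domain. Two details matter for accuracy:

* **Unbiased normalisation.** Windows are aperiodic views cut from a
  larger scene, so the matched content at lag k is attenuated by the
  triangular overlap factor ∏(N−|k|)/N; left uncorrected this shrinks
  subvoxel displacements toward zero by tens of percent for speckle-width
  correlation peaks. The default estimator divides the factor out
  (search is restricted to |k| ≤ N/4, where the correction is mild); the
  plain circular estimator, exact for periodically shifted windows, is
  available as `normalize = "circular"`.
* **Masked boundary windows.** Windows straddling the lung boundary use
  a zero-padded masked normalised cross-correlation whose per-lag
  statistics run over the mask overlap only. Such a window measures the
  displacement of its lung *content*, so its vector is located at the
  mask centroid rather than the window centre; the expansion estimator
  uses these true measurement positions.

The subvoxel refinement is the standard 3-point Gaussian fit per axis
(parabolic as fallback and option). Vector validation uses the
primary-to-secondary peak ratio (default threshold 1.2; the secondary
peak is searched outside a 2-voxel exclusion zone); invalid interior
vectors are replaced by the component-wise median of their valid
26-neighbours and flagged, while boundary vectors are left sparse — as
real maps are near the heart, where cardiac motion decorrelates windows.

Expansion is the divergence of the incremental displacement
(small-strain, first-order), obtained by a local least-squares linear
fit of the vectors over the stencil's measurement positions — exactly
central differences on a regular grid, but unbiased when boundary
vectors sit at mask centroids. Tracking is successive-pair (t → t+1),
each field relative to the moving previous phase; cumulative
displacement from phase 0 is accumulated with grid resampling along the
moving trajectory. No multi-pass window deformation is attempted.

The spatial resolution of the expansion map is roughly two windows
(~64 voxels at defaults). At the desk-scale phantom this is comparable
to the lung radius, so *pointwise* expansion maps carry noise of the
same order as their spatial contrast; aggregated over airway
territories, the regional volumes are accurate to a few percent. This is
a deliberate problem-size trade-off: real acquisitions put many more
windows across the lung, the phantom puts enough to test the chain
within a CI-friendly compute budget (the default study conditions are a
96³ grid, 15 phases, 6 generations; the shift-recovery checks use 128³).

## Airway Tree Link

Lung elements are assigned to the nearest terminal endpoint (Euclidean,
ties to the lowest segment id) — the original linkage rule is not
restated in the source literature, so nearest-endpoint is exposed as the
single strategy behind an interface that admits alternatives. Regional
volume series integrate the expansion over each territory per interval
and accumulate, starting at 0 at phase 0. Two quadratures are provided:
the node-cell method (each node carries its grid cell, optionally
mask-weighted via `node_cell_volumes()`), and the default voxel-level
method used when a lung mask is given — the displacement components are
projected to the grid nodes by local linear fits over their measurement
positions, interpolated trilinearly to every voxel, and their discrete
divergence summed per region. Displacement is nearly linear in space, so
extrapolating *it* into the boundary shell is well conditioned where
extrapolating the divergence is not; this is what keeps whole-lung tidal
recovery within a few percent of the closed form.

`flow_sum()` is a post-order traversal: leaf series are their own
regional series, internal series the sum of their two daughters, so
conservation at every bifurcation holds to round-off by construction —
the test asserts it to 1e−9 to catch traversal bugs, not physics.
Airflow is the finite difference of volume over the phase-time step.
Airway compression is neglected, as appropriate for tidal ventilation.

The expiratory time constant is operational, not a fit: τ is the time
after the start of expiration at which the branch volume first falls
below (1 − threshold) × tidal volume, with linear interpolation between
phase samples and threshold 1 − 1/e exactly. The baseline is the tidal
peak, so the definition is self-consistent when the peak falls between
samples. With 15 samples over a 500 ms breath the crossing recovers a
100 ms constant to ~2.5% (interpolation error of the exponential between
samples). Branches that never reach the threshold, or with non-positive
tidal volume, are flagged invalid rather than erroring. Expiration start
is taken from the ventilation protocol's `t_insp` (ventilator-triggered
acquisition makes protocol time authoritative); a measured-peak option
and a log-linear exponential fit are provided. The threshold is applied
to volume above the series' own end-expiration zero — FRC, not any
PEEP-inflated baseline.

`aeration_map()` broadcasts each segment's cumulative volume to its
centerline points per phase — the quantity used to colour the tree
rendering; exports use linear colour scales with configurable ranges.

## Numerical choices and degenerate inputs

FFT-based filters use periodic boundaries (fields of interest vanish
near volume edges). Eigenvalues of the 3×3 Hessians use the vectorised
trigonometric method with clamping for degenerate (isotropic) voxels.
Zero-variance correlation windows yield flagged invalid vectors, never
exceptions; pure-noise segmentation inputs fail with a degenerate-input
error; non-integer gating ratios, overlapping defects, out-of-grid
trees, disconnected masks and empty phase bins are all errors with
specific messages. All randomness flows from the single spec/config
seed through deterministic sub-seed derivation, and the pipeline
manifest (package version, config, config hash, per-stage summaries)
contains no timestamps, so identical runs are bit-identical.

## Known limitations

* The phantom's speckle is a texture, not propagated phase contrast;
  its lung is a generic ellipsoid; cardiac motion is not modelled.
* Pointwise expansion maps at the default problem size are
  resolution-limited (see above); quantitative claims should be made on
  regional aggregates.
* Image-based segmentation is validated to generation 3–4 at desk
  scale; deeper generations need larger volumes than the phantom's
  default grid.
* The τ estimator assumes monotone-enough expiratory decay between
  samples; oscillatory series (e.g. cardiac contamination) would cross
  early.
* No iterative reconstruction, scatter or beam-hardening correction; no
  airway mechanics (resistance/compliance) modelling.
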