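# lung4dxv

Regional lung function from four-dimensional X-ray velocimetry (4DxV) CT.

Global tests of lung function (FEV1, lung clearance index) cannot say
*where* in the lung function is lost. 4DxV imaging answers that question by
tracking the motion of the speckled lung parenchyma through a
respiratory-gated 4D CT breath series: ventilator-triggered projections are
binned by breath phase and reconstructed into one volume per time point,
the airway tree is segmented from the end-expiration volume, lung tissue
displacement between successive phases is measured by windowed 3D
cross-correlation (X-ray velocimetry, XV), and the local volumetric
expansion — the divergence of the displacement field — is linked to the
airway tree to obtain the airflow through every branch. `lung4dxv`
implements that entire chain for researchers studying regional ventilation
in small-animal models of obstructive lung disease, together with a
synthetic breathing-lung phantom whose ground truth is known in closed
form, so every stage is testable without animal data.

## The method in brief

* **Gated reconstruction.** Frames acquired at rate `f` (frames/s) under
  ventilation at `R` breaths/min land on `f · 60 / R` fixed points of the
  breath (15 bins at 30 fps and 120 breaths/min). Each bin's projections
  are reconstructed by cone-beam filtered backprojection (FDK: cosine
  weighting, row-wise ramp filtering, distance-weighted backprojection)
  on a grid whose voxel is the effective pixel
  `p · R1 / R2` (detector pitch demagnified to the isocenter).
* **Airway segmentation.** Multiscale Hessian vesselness (Frangi measure
  on the scale-normalised eigenvalues, dark-tube convention for air-filled
  airways), flood fill from a tracheal seed, topology-preserving 3D
  thinning, and pruning into a rooted binary airway tree with per-point
  radii from the distance transform.
* **Velocimetry (XV).** Band-passed volumes are compared over 32³-voxel
  interrogation windows with 50% overlap; each window's normalised
  cross-correlation peak, refined by a 3-point Gaussian fit, gives a
  subvoxel displacement vector with a peak-ratio quality score. Windows
  that straddle the lung boundary use a masked, zero-padded correlation so
  the chest wall cannot bias the vector. The expansion field is the
  divergence of the displacement field, estimated by local least squares
  over the interrogation grid.
* **Airway Tree Link (ATL).** Lung tissue is partitioned among the
  terminal airways (nearest terminal endpoint); integrating the expansion
  over each territory gives the air volume supplied through each terminal,
  and summing recursively up the tree — flow through a parent equals the
  sum of its two daughters — yields the full per-branch airflow series.
  The regional expiratory time constant τ is the time after the start of
  expiration for a branch's expired volume to reach 1 − 1/e (≈63%) of its
  tidal volume.

## Worked example

Simulate the default breathing-lung phantom (96³ voxels, 6 airway
generations, 15 breath phases, 120 breaths/min), track it with XV, and run
the ATL analysis:

```r
library(lung4dxv)

spec <- phantom_spec(grid_shape = c(96, 96, 96), tree_generations = 6,
                     noise_sigma = 0, seed = 1)
phantom <- simulate_breath_series(spec)
print(phantom)
#> <lung_phantom> 15 phases, grid 96x96x96, 127 airway segments
#>   peak tidal volume (truth): 4.237e+04

track <- track_breath(phantom$volumes, xv_params(), phantom$lung_mask)
print(track)
#> <xv_track> 14 interval fields on 125 nodes

labels   <- assign_regions(phantom$lung_mask, phantom$tree)
regional <- regional_volumes(track$expansions, labels, track$phase_times,
                             lung_mask = phantom$lung_mask)
flow     <- flow_sum(phantom$tree, regional)
glance(flow)
#> # A tibble: 1 x 4
#>   n_segments n_phases tidal_volume peak_time
#> 1        127       15       40983.      233.

taus <- expiratory_time_constant(flow, spec$ventilation)
dplyr::summarise(taus, median_tau = median(tau[valid]), valid = sum(valid))
#> # A tibble: 1 x 2
#>   median_tau valid
#> 1       80.5   127
```

The measured whole-lung tidal volume (40 983 voxels³, read off the trachea
branch at peak inspiration, t = 233 ms) recovers the phantom's closed-form
ground truth (42 370) to within ~3%, and the median branch expiratory time
constant (80.5 ms) recovers the phantom's programmed 80 ms. `autoplot()`
methods draw the airway tree, displacement and expansion fields, branch
volume series and τ-coloured tree; `run_pipeline()` executes the whole
chain from a YAML configuration and writes volumes (NIfTI/TIFF), VTK
polyline trees, CSV field/branch tables and a reproducibility manifest.
A thin command-line wrapper lives at `inst/cli/lung4dxv.R`.

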