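#' Ventilator protocol
#'
#' Pressure-controlled ventilation settings used both as acquisition metadata
#' (gating is ventilator-triggered) and by the breathing-lung phantom.
#' Defaults are a typical small-animal airway-analysis protocol: PIP
#' 12 / PEEP 2 cm H2O, 250/250 ms inspiration/expiration, 120 breaths/min,
#' imaging at 30 frames/s.
#'
#' @param pip peak inspiratory pressure (cm H2O)
#' @param peep positive end-expiratory pressure (cm H2O)
#' @param t_insp,t_exp inspiratory and expiratory times (ms); must sum to
#'   `60000 / respiratory_rate`
#' @param respiratory_rate breaths per minute
#' @param frame_rate imaging frame rate (frames/s)
#' @return an object of class `ventilation_protocol` (a named list)
#' @examples
#' ventilation_protocol()
#' ventilation_protocol(t_insp = 150, t_exp = 350)
#' @export
ventilation_protocol <- function(pip = 12, peep = 2, t_insp = 250,
                                 t_exp = 250, respiratory_rate = 120,
                                 frame_rate = 30) {
  vals <- c(pip = pip, peep = peep, t_insp = t_insp, t_exp = t_exp,
            respiratory_rate = respiratory_rate, frame_rate = frame_rate)
  if (any(vals <= 0)) abort("all ventilation protocol fields must be > 0")
  period <- 60000 / respiratory_rate
  if (abs(t_insp + t_exp - period) > 1e-6)
    abort(sprintf(
      "t_insp + t_exp must equal 60000 / respiratory_rate (%g ms, got %g ms)",
      period, t_insp + t_exp))
  structure(
    list(pip = pip, peep = peep, t_insp = t_insp, t_exp = t_exp,
         respiratory_rate = respiratory_rate, frame_rate = frame_rate,
         period = period),
    class = "ventilation_protocol"
  )
}

#' @export
print.ventilation_protocol <- function(x, ...) {
  cat(sprintf(
    "<ventilation_protocol> PIP %g / PEEP %g cm H2O, %g/%g ms I:E, %g bpm, %g fps\n",
    x$pip, x$peep, x$t_insp, x$t_exp, x$respiratory_rate, x$frame_rate))
  invisible(x)
}

#' Respiratory rate implied by inspiratory/expiratory times
#'
#' @param t_insp,t_exp inspiratory and expiratory times (ms)
#' @return breaths per minute (`60000 / (t_insp + t_exp)`)
#' @examples
#' breaths_per_minute(250, 250) # 120
#' @export
breaths_per_minute <- function(t_insp, t_exp) {
  if (t_insp <= 0 || t_exp <= 0) abort("breath-phase times must be > 0")
  60000 / (t_insp + t_exp)
}

#' Regional ventilation defect
#'
#' A spherical region of patchy disease: expansion inside is scaled down by
#' `expansion_scale` and the local expiratory time constant is slowed by
#' `tau_scale`.  With `support = "sphere"` the defect weight is an analytic
#' smoothstep on the sphere; with `support = "regions"` the defect covers the
#' whole territory of every terminal airway whose endpoint falls inside the
#' sphere, so each ventilation unit carries a single time constant.
#'
#' @param center defect centre, voxel coordinates `c(z, y, x)` (0-based)
#' @param radius sphere radius (voxels)
#' @param expansion_scale multiplicative expansion factor in (0, 1]
#' @param tau_scale multiplicative expiratory time-constant factor, >= 1
#' @param support `"sphere"` or `"regions"` (see Details)
#' @param edge_width half-width of the smooth sphere edge (voxels)
#' @return an object of class `defect_spec`
#' @export
defect_spec <- function(center, radius, expansion_scale = 1, tau_scale = 1,
                        support = c("sphere", "regions"), edge_width = 3) {
  support <- match.arg(support)
  if (length(center) != 3) abort("`center` must be c(z, y, x)")
  if (radius <= 0) abort("`radius` must be > 0")
  if (expansion_scale <= 0 || expansion_scale > 1)
    abort("`expansion_scale` must be in (0, 1] (a defect reduces expansion)")
  if (tau_scale < 1) abort("`tau_scale` must be >= 1 (a defect slows expiration)")
  structure(
    list(center = as.numeric(center), radius = radius,
         expansion_scale = expansion_scale, tau_scale = tau_scale,
         support = support, edge_width = edge_width),
    class = "defect_spec"
  )
}

#' Synthetic breathing-lung phantom specification
#'
#' Full parameterisation of the synthetic 4D dataset: a speckled parenchyma
#' inside an ellipsoidal lung envelope, an embedded air-filled binary airway
#' tree, and a smooth analytic displacement field over `n_phases` breath
#' phases with optional regional defects.  Identical specs (including
#' `seed`) produce bit-identical datasets.
#'
#' @param grid_shape voxels per axis, `c(nz, ny, nx)`
#' @param voxel_size edge length of a voxel (arbitrary length unit; volumes
#'   are reported in this unit cubed)
#' @param tree_generations number of bifurcation generations (0 = trachea
#'   only); a full binary tree has `2^g` terminal segments
#' @param tidal_fraction peak volumetric strain at the lung centre,
#'   dimensionless in (0, 0.5)
#' @param speckle_grain autocorrelation FWHM of the parenchymal speckle
#'   texture (voxels)
#' @param noise_sigma additive Gaussian intensity noise per phase
#' @param n_phases number of respiratory time bins (>= 2)
#' @param base_tau baseline regional expiratory time constant (ms)
#' @param center_taper strength in `[0, 1)` of the centre-weighted expansion
#'   taper (0 = spatially uniform dilation; larger values concentrate
#'   expansion at the lobe centre)
#' @param defects list of [defect_spec()] objects (non-overlapping spheres)
#' @param ventilation a [ventilation_protocol()]
#' @param seed integer seed; all phantom randomness derives from it
#' @return an object of class `phantom_spec`
#' @examples
#' spec <- phantom_spec(grid_shape = c(48, 48, 48), tree_generations = 3)
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_size = 1,
                         tree_generations = 6, tidal_fraction = 0.2,
                         speckle_grain = 5, noise_sigma = 0.02,
                         n_phases = 15, base_tau = 80, center_taper = 0.4,
                         defects = list(),
                         ventilation = ventilation_protocol(), seed = 1L) {
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    abort("`grid_shape` must be c(nz, ny, nx), all >= 8")
  if (n_phases < 2) abort("`n_phases` must be >= 2")
  if (tree_generations < 0) abort("`tree_generations` must be >= 0")
  if (tidal_fraction < 0 || tidal_fraction >= 0.5)
    abort("`tidal_fraction` must be in [0, 0.5)")
  if (center_taper < 0 || center_taper >= 1)
    abort("`center_taper` must be in [0, 1)")
  if (base_tau <= 0) abort("`base_tau` must be > 0 (ms)")
  if (!inherits(ventilation, "ventilation_protocol"))
    abort("`ventilation` must be a ventilation_protocol()")
  if (!all(vapply(defects, inherits, TRUE, "defect_spec")))
    abort("`defects` must be a list of defect_spec() objects")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         tree_generations = as.integer(tree_generations),
         tidal_fraction = tidal_fraction, speckle_grain = speckle_grain,
         noise_sigma = noise_sigma, n_phases = as.integer(n_phases),
         base_tau = base_tau, center_taper = center_taper,
         defects = defects, ventilation = ventilation,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> grid %s, %d generations, %d phases, tidal %.2f, seed %d\n",
    paste(x$grid_shape, collapse = "x"), x$tree_generations, x$n_phases,
    x$tidal_fraction, x$seed))
  if (length(x$defects))
    cat(sprintf("  %d defect(s)\n", length(x$defects)))
  invisible(x)
}

#' Breath-phase time points of a phantom
#'
#' Phase sampling times within one breath: `n_phases` equally spaced times
#' starting at end-expiration, spanning `[0, period)` ms.
#'
#' @param spec a [phantom_spec()]
#' @return numeric vector of times (ms)
#' @export
phase_times <- function(spec) {
  period <- spec$ventilation$period
  seq(0, period, length.out = spec$n_phases + 1)[seq_len(spec$n_phases)]
}
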