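# Analytic breathing motion: ground-truth displacement and expansion.
#
# u(x, t) = a * g(rho) * (x - c) * S(x, t)
#   rho     ellipsoid-normalised radius of the lung envelope
#   g(rho)  = 1 - k rho^2 / 2   (k = center_taper; lobe centre expands most)
#   a       = tidal_fraction / 3 (peak volumetric strain tidal_fraction)
#   S(x, t) mixes base and defect temporal factors with smooth weights.
# Divergence in closed form:
#   div u = a (3 - (5k/2) rho^2) S + a g(rho) (x - c) . grad S

#' Breath temporal profile
#'
#' Raised-cosine rise from 0 to 1 over the inspiratory time, then
#' exponential decay `exp(-(t - t_insp)/tau)` over expiration, so the
#' expiratory time constant is a direct parameter of the phantom.
#'
#' @param t time within the breath (ms), in `[0, period]`
#' @param t_insp inspiratory time (ms)
#' @param tau expiratory time constant (ms)
#' @return dimensionless profile value(s) in `[0, 1]`
#' @export
breath_profile <- function(t, t_insp, tau) {
  ifelse(t <= t_insp,
         (1 - cos(pi * t / t_insp)) / 2,
         exp(-(t - t_insp) / tau))
}

# smoothstep in [0,1] (argument order keeps array dims intact)
smoothstep <- function(t) {
  t <- pmax(pmin(t, 1), 0)
  t * t * (3 - 2 * t)
}

# central-difference gradient of a smooth array, voxel spacing 1
grad3 <- function(a) {
  d <- dim(a)
  gz <- (circ_shift3(a, c(-1, 0, 0)) - circ_shift3(a, c(1, 0, 0))) / 2
  gy <- (circ_shift3(a, c(0, -1, 0)) - circ_shift3(a, c(0, 1, 0))) / 2
  gx <- (circ_shift3(a, c(0, 0, -1)) - circ_shift3(a, c(0, 0, 1))) / 2
  list(z = gz, y = gy, x = gx)
}

#' Ground-truth motion model of a phantom
#'
#' Precomputes the static spatial factors of the analytic displacement
#' field, returning closures that evaluate the displacement and its
#' divergence at any time within the breath.
#'
#' @param spec a [phantom_spec()]
#' @param tree an [airway_tree()]; generated from `spec` when `NULL`
#'   (required only when a defect uses `support = "regions"`)
#' @param regions optional precomputed [phantom_regions()]
#' @return an object of class `phantom_motion`: list with `displacement(t)`
#'   (list of arrays uz, uy, ux, voxels), `divergence(t)` (array, per-voxel
#'   volumetric strain), `terminal_tau` (tibble of per-terminal expiratory
#'   time constants) and `period`
#' @export
phantom_motion <- function(spec, tree = NULL, regions = NULL) {
  d <- spec$grid_shape
  ctr <- (d - 1) / 2
  k <- spec$center_taper
  a <- spec$tidal_fraction / 3
  rho <- lung_envelope_rho(spec)
  g <- 1 - k * rho^2 / 2
  div0 <- a * (3 - (5 * k / 2) * rho^2)
  ag <- a * g
  grids <- axis_grids(d)
  xz <- grids$z - ctr[1]; xy <- grids$y - ctr[2]; xx <- grids$x - ctr[3]

  needs_tree <- any(vapply(spec$defects, function(df) df$support == "regions",
                           TRUE))
  if (needs_tree && is.null(tree)) tree <- generate_airway_tree(spec)
  if (needs_tree && is.null(regions)) regions <- phantom_regions(tree, spec)

  defects <- lapply(spec$defects, function(df) {
    if (df$support == "sphere") {
      r <- sqrt((grids$z - df$center[1])^2 + (grids$y - df$center[2])^2 +
                  (grids$x - df$center[3])^2)
      h <- df$edge_width
      w <- 1 - smoothstep((r - df$radius + h) / (2 * h))
      # analytic d/dr of the smoothstep edge
      tt <- pmin(1, pmax(0, (r - df$radius + h) / (2 * h)))
      dw <- -(6 * tt * (1 - tt)) / (2 * h)
      rs <- pmax(r, 1e-9)
      gw <- list(z = dw * (grids$z - df$center[1]) / rs,
                 y = dw * (grids$y - df$center[2]) / rs,
                 x = dw * (grids$x - df$center[3]) / rs)
      term_in <- integer()
      if (!is.null(tree)) {
        ends <- terminal_endpoints(tree)
        term_in <- ends$id[(ends$z - df$center[1])^2 +
                             (ends$y - df$center[2])^2 +
                             (ends$x - df$center[3])^2 <= df$radius^2]
      }
    } else {
      # "regions" support: the defect covers the whole territory of every
      # terminal whose endpoint falls inside the sphere, with a sharp
      # weight, so each ventilation unit carries exactly one time constant
      # (the strain then jumps across territory boundaries, as in patchy
      # disease; the surface sheet term is omitted from the divergence,
      # which is the one-sided closed form inside each territory)
      ends <- terminal_endpoints(tree)
      term_in <- ends$id[(ends$z - df$center[1])^2 +
                           (ends$y - df$center[2])^2 +
                           (ends$x - df$center[3])^2 <= df$radius^2]
      w <- array(0, d)
      w[regions$region_labels %in% term_in] <- 1
      gw <- NULL
    }
    # x~ . grad w, the defect's contribution to the divergence
    p <- if (is.null(gw)) array(0, d)
         else xz * gw$z + xy * gw$y + xx * gw$x
    list(w = w, p = p, es = df$expansion_scale,
         tau = spec$base_tau * df$tau_scale, terminals = term_in)
  })
  wsum <- array(0, d)
  for (df in defects) wsum <- wsum + df$w
  if (max(wsum) > 1 + 1e-6) abort("phantom defects must not overlap")

  protocol <- spec$ventilation
  check_t <- function(t) {
    if (t < 0 || t > protocol$period)
      abort(sprintf("phase_time %g ms outside breath period [0, %g]",
                    t, protocol$period))
  }
  factors <- function(t) {
    f0 <- breath_profile(t, protocol$t_insp, spec$base_tau)
    fi <- vapply(defects, function(df)
      breath_profile(t, protocol$t_insp, df$tau), 0)
    list(f0 = f0, fi = fi)
  }
  S_of <- function(t) {
    f <- factors(t)
    S <- (1 - wsum) * f$f0
    for (i in seq_along(defects))
      S <- S + defects[[i]]$w * defects[[i]]$es * f$fi[i]
    S
  }
  displacement <- function(t) {
    check_t(t)
    S <- S_of(t)
    list(uz = ag * xz * S, uy = ag * xy * S, ux = ag * xx * S)
  }
  divergence <- function(t) {
    check_t(t)
    f <- factors(t)
    S <- S_of(t)
    out <- div0 * S
    for (i in seq_along(defects))
      out <- out + ag * (defects[[i]]$es * f$fi[i] - f$f0) * defects[[i]]$p
    out
  }
  term_tau <- NULL
  if (!is.null(tree)) {
    ids <- sort(terminal_ids(tree))
    tau <- rep(spec$base_tau, length(ids))
    for (df in defects) tau[ids %in% df$terminals] <- df$tau
    term_tau <- tibble(id = ids, tau = tau)
  }
  structure(
    list(displacement = displacement, divergence = divergence,
         terminal_tau = term_tau, period = protocol$period, spec = spec),
    class = "phantom_motion"
  )
}

#' Analytic ground-truth displacement at one breath phase
#'
#' @param spec a [phantom_spec()]
#' @param phase_time time within the breath (ms), `0 <= t <= period`
#' @param tree,regions optional precomputed tree / region partition
#' @return list with `uz`, `uy`, `ux` (displacement arrays, voxels) and
#'   `divergence` (per-voxel volumetric strain array)
#' @export
analytic_displacement <- function(spec, phase_time, tree = NULL,
                                  regions = NULL) {
  m <- phantom_motion(spec, tree, regions)
  u <- m$displacement(phase_time)
  c(u, list(divergence = m$divergence(phase_time)))
}
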