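# Rendering of the static end-expiration phantom: ellipsoidal lung envelope,
# band-limited speckle parenchyma, dark air-filled airway lumens.

lung_envelope_rho <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d - 1) / 2
  semi <- 0.42 * d
  g <- axis_grids(d)
  sqrt(((g$z - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
         ((g$x - ctr[3]) / semi[3])^2)
}

#' Lung envelope mask of a phantom
#' @param spec a [phantom_spec()]
#' @return logical 3D array, `TRUE` inside the ellipsoidal lung envelope
#' @export
lung_envelope_mask <- function(spec) lung_envelope_rho(spec) <= 1

# Paint airway lumens: union of balls along every centerline
rasterize_lumen <- function(tree, dim) {
  lum <- array(FALSE, dim)
  for (i in seq_len(nrow(tree$segments))) {
    pts <- tree$segments$points[[i]]
    for (j in seq_len(nrow(pts))) {
      p <- pts[j, ]
      r <- p[4]
      zr <- max(0, floor(p[1] - r)):min(dim[1] - 1, ceiling(p[1] + r))
      yr <- max(0, floor(p[2] - r)):min(dim[2] - 1, ceiling(p[2] + r))
      xr <- max(0, floor(p[3] - r)):min(dim[3] - 1, ceiling(p[3] + r))
      dz2 <- (zr - p[1])^2
      dy2 <- (yr - p[2])^2
      dx2 <- (xr - p[3])^2
      ball <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= r^2
      sub <- lum[zr + 1, yr + 1, xr + 1, drop = FALSE]
      lum[zr + 1, yr + 1, xr + 1] <- sub | ball
    }
  }
  lum
}

#' Phantom masks and terminal-region labels
#'
#' Rasterises the airway lumens of `tree` and labels every parenchymal voxel
#' with the id of its supplying terminal airway (nearest terminal endpoint,
#' ties broken towards the lowest id) — the generator's own ground-truth
#' region partition.
#'
#' @param tree an [airway_tree()]
#' @param spec the [phantom_spec()] the tree was generated from
#' @return list with `lung_mask` (parenchyma: envelope minus lumen),
#'   `lumen_mask`, and integer `region_labels` (0 outside the lung)
#' @export
phantom_regions <- function(tree, spec) {
  d <- spec$grid_shape
  env <- lung_envelope_mask(spec)
  lum <- rasterize_lumen(tree, d)
  lung <- env & !lum
  ends <- terminal_endpoints(tree)
  g <- axis_grids(d)
  idx <- which(lung)
  vz <- g$z[idx]; vy <- g$y[idx]; vx <- g$x[idx]
  best <- rep(Inf, length(idx))
  lab <- integer(length(idx))
  for (k in order(ends$id)) {
    d2 <- (vz - ends$z[k])^2 + (vy - ends$y[k])^2 + (vx - ends$x[k])^2
    take <- d2 < best
    best[take] <- d2[take]
    lab[take] <- ends$id[k]
  }
  labels <- array(0L, d)
  labels[idx] <- lab
  list(lung_mask = lung, lumen_mask = lum, region_labels = labels)
}

#' Render the end-expiration reference volume
#'
#' Parenchyma is a band-limited random speckle texture (autocorrelation
#' FWHM ~ `speckle_grain`) on a bright baseline, airway lumens and the
#' region outside the lung envelope are darker, emulating the air/tissue
#' contrast of phase-contrast lung CT.  Deterministic for a fixed spec seed.
#'
#' @param tree an [airway_tree()]
#' @param spec the [phantom_spec()]
#' @param regions optional precomputed [phantom_regions()] output
#' @return numeric 3D array of intensities (roughly in \[0, 1\])
#' @export
render_reference_volume <- function(tree, spec, regions = NULL) {
  d <- spec$grid_shape
  if (is.null(regions)) regions <- phantom_regions(tree, spec)
  set.seed(derive_seed(spec$seed, 2L))
  noise <- array(rnorm(prod(d)), d)
  sigma_g <- spec$speckle_grain / (2 * sqrt(2 * log(2)) * sqrt(2))
  speck <- gaussian_smooth3(noise, sigma_g)
  speck <- tanh(speck / sd(speck)) # bounded modulation: parenchyma (a
  # tissue/air mixture) never gets as dark as a pure-air lumen
  vol <- array(0.45, d) # textureless soft tissue outside the lung
  env <- regions$lung_mask | regions$lumen_mask
  vol[env] <- 0.55 + 0.15 * speck[env]
  vol[regions$lumen_mask] <- 0.05
  vol
}
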