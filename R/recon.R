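#' Cone-beam acquisition geometry
#'
#' Source-to-isocenter and source-to-detector distances with flat-detector
#' pixel pitch.  Defaults follow a laboratory propagation-based setup:
#' R1 = 0.36 m, R2 = 3.0 m, 194 um detector pixels.
#'
#' @param r1 source-to-isocenter distance (m)
#' @param r2 source-to-detector distance (m); must exceed `r1`
#' @param detector_pitch detector pixel pitch (m)
#' @param detector_shape detector pixels as `c(nv, nu)` (rows = vertical)
#' @return an object of class `recon_geometry`
#' @export
recon_geometry <- function(r1 = 0.36, r2 = 3.0, detector_pitch = 194e-6,
                           detector_shape = c(128, 128)) {
  if (r1 <= 0 || r2 <= 0) abort("distances must be positive")
  if (r1 >= r2) abort("geometry requires r1 < r2 (isocenter between source and detector)")
  if (detector_pitch <= 0) abort("`detector_pitch` must be positive")
  structure(
    list(r1 = r1, r2 = r2, detector_pitch = detector_pitch,
         detector_shape = as.integer(detector_shape)),
    class = "recon_geometry"
  )
}

#' Effective pixel size at the isocenter
#'
#' Detector pitch demagnified to the rotation axis:
#' `detector_pitch * r1 / r2`.  The reconstruction grid uses this as its
#' voxel size.
#'
#' @param geometry a [recon_geometry()]
#' @return length per pixel (same unit as the geometry distances)
#' @examples
#' effective_pixel_size(recon_geometry()) # 194e-6 * 0.36 / 3 = 23.28e-6
#' @export
effective_pixel_size <- function(geometry) {
  geometry$detector_pitch * geometry$r1 / geometry$r2
}

#' Ventilator gating schedule
#'
#' Acquisition is triggered by the ventilator, so frames land at fixed
#' points of the breathing cycle and bin into
#' `frame_rate * 60 / respiratory_rate` time points per breath.
#'
#' @param frame_rate frames per second
#' @param respiratory_rate breaths per minute; `frame_rate * 60` must be an
#'   exact multiple of it, else gating would drift across breaths
#' @return an object of class `gating_schedule` with the derived `n_phases`
#' @examples
#' gating_schedule(30, 120)$n_phases # 15
#' @export
gating_schedule <- function(frame_rate = 30, respiratory_rate = 120) {
  if (frame_rate <= 0 || respiratory_rate <= 0)
    abort("rates must be positive")
  n <- frame_rate * 60 / respiratory_rate
  if (abs(n - round(n)) > 1e-9)
    abort(sprintf(
      "frame_rate * 60 / respiratory_rate = %g is not an integer; gating would drift",
      n))
  structure(
    list(frame_rate = frame_rate, respiratory_rate = respiratory_rate,
         n_phases = as.integer(round(n))),
    class = "gating_schedule"
  )
}

#' Time bins per breath of a gating schedule
#'
#' @param schedule a [gating_schedule()]
#' @return integer count of respiratory time bins
#' @examples
#' phases_per_breath(gating_schedule(30, 120)) # 15
#' phases_per_breath(gating_schedule(30, 60))  # 30
#' @export
phases_per_breath <- function(schedule) schedule$n_phases

#' Set of tagged cone-beam projections
#'
#' @param images numeric array `c(nv, nu, n)` of projection images
#' @param angles projection angles in degrees, in `[0, 360)`
#' @param phase_tags integer respiratory time-bin index per projection
#'   (0-based)
#' @return an object of class `projection_set`
#' @export
projection_set <- function(images, angles, phase_tags) {
  if (length(dim(images)) != 3) abort("`images` must be a 3D array (nv, nu, n)")
  n <- dim(images)[3]
  if (length(angles) != n || length(phase_tags) != n)
    abort("`angles` and `phase_tags` must have one entry per projection")
  if (any(angles < 0 | angles >= 360)) abort("angles must lie in [0, 360)")
  structure(
    list(images = images, angles = as.numeric(angles),
         phase_tags = as.integer(phase_tags)),
    class = "projection_set"
  )
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d projections of %dx%d, %d phase tag(s)\n",
              dim(x$images)[3], dim(x$images)[1], dim(x$images)[2],
              length(unique(x$phase_tags))))
  invisible(x)
}

#' Simulate cone-beam projections of a volume
#'
#' Line-integral forward projection of a 3D volume (or of a breathing
#' [volume4d()]) in the geometry of [recon_geometry()].  The volume's voxel
#' size is taken to be the effective pixel size of the geometry.  When a
#' [gating_schedule()] is supplied, frame `i` is tagged with breath phase
#' `i mod n_phases` (ventilator-triggered acquisition) and, for a 4D input,
#' the tagged phase's volume is projected.
#'
#' @param volume numeric 3D array or a [volume4d()]
#' @param geometry a [recon_geometry()]
#' @param angles projection angles (degrees) per frame
#' @param schedule optional [gating_schedule()] used to assign phase tags
#' @param step ray sampling step (voxels)
#' @return a [projection_set()] (line integrals in intensity x voxel units)
#' @export
forward_project <- function(volume, geometry, angles, schedule = NULL,
                            step = 0.5) {
  if (!inherits(geometry, "recon_geometry")) abort("invalid geometry")
  is4d <- inherits(volume, "volume4d")
  nfr <- length(angles)
  nph <- if (is.null(schedule)) 1L else schedule$n_phases
  tags <- (seq_len(nfr) - 1L) %% nph
  if (is4d && is.null(schedule))
    abort("projecting a volume4d requires a gating schedule")
  if (is4d && nph != n_phases(volume))
    abort("schedule n_phases must match the number of volume phases")
  eff <- effective_pixel_size(geometry)
  r1v <- geometry$r1 / eff
  r2v <- geometry$r2 / eff
  pitchv <- geometry$detector_pitch / eff # = r2/r1, detector pixel in voxels
  nv <- geometry$detector_shape[1]
  nu <- geometry$detector_shape[2]
  imgs <- array(0, c(nv, nu, nfr))
  if (is4d) {
    for (ph in unique(tags)) {
      sel <- which(tags == ph)
      vol <- volume$phases[[ph + 1L]]
      imgs[, , sel] <- cpp_forward_project(vol, dim(vol), r1v, r2v, pitchv,
                                           nu, nv, angles[sel] * pi / 180,
                                           step)
    }
  } else {
    assert_volume3(volume)
    imgs[] <- cpp_forward_project(volume, dim(volume), r1v, r2v, pitchv,
                                  nu, nv, angles * pi / 180, step)
  }
  projection_set(imgs, angles %% 360, tags)
}

#' Bin projections by respiratory phase
#'
#' Partitions a tagged projection set into one set per breath time bin.
#' Every projection lands in exactly one bin; when acquisition covers whole
#' breaths the bins have equal counts.
#'
#' @param projections a [projection_set()]
#' @param schedule a [gating_schedule()]
#' @return list of `n_phases` [projection_set()]s, ordered by time bin
#' @examples
#' # 6000 projections at 30 fps / 120 bpm -> 15 bins of 400
#' @export
bin_projections_by_phase <- function(projections, schedule) {
  nph <- schedule$n_phases
  tags <- projections$phase_tags
  if (any(tags < 0 | tags >= nph))
    abort("phase tags inconsistent with the gating schedule")
  counts <- tabulate(tags + 1L, nph)
  if (any(counts == 0))
    abort(sprintf("no projections for phase bin(s): %s",
                  paste(which(counts == 0) - 1L, collapse = ", ")))
  lapply(seq_len(nph) - 1L, function(ph) {
    sel <- which(tags == ph)
    projection_set(projections$images[, , sel, drop = FALSE],
                   projections$angles[sel], projections$phase_tags[sel])
  })
}

# Kak & Slaney discrete ramp-filter kernel, unit sample spacing
ramp_kernel <- function(n) {
  h <- numeric(2 * n)
  idx <- seq_len(2 * n) - 1
  k <- ifelse(idx <= n, idx, idx - 2 * n) # symmetric lags
  h[k == 0] <- 1 / 4
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd])^2
  h
}

#' Cone-beam filtered backprojection (FDK)
#'
#' Reconstructs one phase volume from its projections: cosine pre-weighting,
#' row-wise ramp filtering in the frequency domain (zero-padded), and
#' distance-weighted backprojection.  Projections need not be uniformly
#' spaced in angle; each is weighted by its angular gap.
#'
#' @param projections a [projection_set()] (a single phase)
#' @param geometry a [recon_geometry()]
#' @param out_shape reconstruction grid `c(nz, ny, nx)`; voxel size is the
#'   effective pixel size of the geometry
#' @return numeric 3D array
#' @export
fdk_reconstruct <- function(projections, geometry, out_shape) {
  if (!inherits(projections, "projection_set")) abort("invalid projection set")
  n <- dim(projections$images)[3]
  if (n < 1) abort("empty projection set")
  eff <- effective_pixel_size(geometry)
  r1v <- geometry$r1 / eff
  nv <- dim(projections$images)[1]
  nu <- dim(projections$images)[2]
  # isocenter-plane detector coordinates (voxel units, spacing 1)
  uu <- (seq_len(nu) - (nu + 1) / 2)
  vv <- (seq_len(nv) - (nv + 1) / 2)
  w <- r1v / sqrt(r1v^2 + outer(vv^2, uu^2, `+`))
  npad <- 2^ceiling(log2(2 * nu))
  H <- Re(fft(c(ramp_kernel(npad / 2))))
  ord <- order(projections$angles)
  ang <- projections$angles[ord] * pi / 180
  # per-projection angular gap (radians), circular
  if (n > 1) {
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    dbeta <- (gaps + c(gaps[n], gaps[-n])) / 2
  } else {
    dbeta <- 2 * pi
  }
  filt <- array(0, c(nv, nu, n))
  for (i in seq_len(n)) {
    p <- projections$images[, , ord[i]] * w
    P <- matrix(0, nv, npad)
    P[, seq_len(nu)] <- p
    Q <- t(stats::mvfft(t(P)))
    Q <- Q * matrix(H, nv, npad, byrow = TRUE)
    q <- Re(t(stats::mvfft(t(Q), inverse = TRUE))) / npad
    filt[, , i] <- q[, seq_len(nu)]
  }
  cpp_backproject(filt, dim(filt), ang, dbeta / 2, r1v, 1.0,
                  as.integer(out_shape))
}

#' Reconstruct a gated 4D CT series
#'
#' Bins a tagged projection set by breath phase and runs [fdk_reconstruct()]
#' on each bin, returning the phases in time order.
#'
#' @inheritParams bin_projections_by_phase
#' @inheritParams fdk_reconstruct
#' @return a [volume4d()]; phase times follow the schedule's breath period
#' @export
reconstruct_4d <- function(projections, schedule, geometry, out_shape) {
  bins <- bin_projections_by_phase(projections, schedule)
  vols <- lapply(bins, fdk_reconstruct, geometry = geometry,
                 out_shape = out_shape)
  period <- 60000 / schedule$respiratory_rate
  times <- (seq_along(bins) - 1) * period / length(bins)
  volume4d(vols, voxel_size = effective_pixel_size(geometry),
           phase_times = times)
}
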