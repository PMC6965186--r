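#' X-ray velocimetry parameters
#'
#' Windowed 3D cross-correlation settings.  Defaults follow standard
#' practice for lung speckle: 32^3-voxel interrogation regions with 50%
#' overlap, light Gaussian smoothing, and a radial band-pass that keeps the
#' speckle scale.
#'
#' @param window interrogation window edge (voxels), >= 8
#' @param overlap fraction of window overlap between neighbouring regions,
#'   in `[0, 1)`; `window * (1 - overlap)` must be a whole number of voxels
#' @param smooth_sigma Gaussian pre-smoothing sigma (voxels)
#' @param band_low,band_high radial band-pass edges (cycles/voxel),
#'   `band_low < band_high <= 0.5`
#' @param peak_quality_min minimum primary/secondary correlation peak ratio
#'   for a vector to be accepted
#' @param fill_invalid replace invalid interior vectors by the median of
#'   their valid 26-neighbours (boundary nodes are left sparse)
#' @param refine subvoxel peak estimator: 3-point `"gaussian"` (standard
#'   PIV choice) or `"parabolic"`
#' @param normalize correlation normalization, see [correlate_pair()]
#' @return an object of class `xv_params`
#' @export
xv_params <- function(window = 32, overlap = 0.5, smooth_sigma = 1,
                      band_low = 0.01, band_high = 0.25,
                      peak_quality_min = 1.2, fill_invalid = TRUE,
                      refine = c("gaussian", "parabolic"),
                      normalize = c("unbiased", "circular")) {
  refine <- match.arg(refine)
  normalize <- match.arg(normalize)
  if (window < 8) abort("`window` must be >= 8 voxels")
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1)")
  step <- window * (1 - overlap)
  if (abs(step - round(step)) > 1e-9)
    abort("window * (1 - overlap) must be an integer number of voxels")
  if (band_low >= band_high) abort("`band_low` must be < `band_high`")
  structure(
    list(window = as.integer(window), overlap = overlap,
         smooth_sigma = smooth_sigma, band_low = band_low,
         band_high = band_high, peak_quality_min = peak_quality_min,
         fill_invalid = fill_invalid, refine = refine,
         normalize = normalize, step = as.integer(round(step))),
    class = "xv_params"
  )
}

#' Pre-process a CT volume for velocimetry
#'
#' Gaussian smoothing to reduce noise followed by a radial frequency-domain
#' band-pass that enhances speckle visibility; the result is zero-mean
#' (within `lung_mask` when given).
#'
#' @param volume numeric 3D array
#' @param params an [xv_params()]
#' @param lung_mask optional logical array; the zero-mean normalisation is
#'   computed over this mask
#' @return filtered numeric 3D array
#' @export
xv_preprocess <- function(volume, params = xv_params(), lung_mask = NULL) {
  assert_volume3(volume)
  if (params$band_high > 0.5)
    abort("`band_high` exceeds the Nyquist frequency (0.5 cycles/voxel)")
  if (!is.null(lung_mask)) {
    # flatten everything outside the mask (chest wall, airway lumens) to
    # the parenchymal mean so strong anatomical edges cannot leak into the
    # pass band and bias vectors near the lung boundary
    volume[!lung_mask] <- mean(volume[lung_mask])
  }
  out <- gaussian_smooth3(volume, params$smooth_sigma)
  out <- bandpass3(out, params$band_low, params$band_high)
  m <- if (is.null(lung_mask)) mean(out) else mean(out[lung_mask])
  out - m
}

#' Interrogation grid for a volume shape
#'
#' Nodes sit at window centres, stepping by `window * (1 - overlap)`, with
#' every window fully inside the volume.
#'
#' @param shape volume shape `c(nz, ny, nx)`
#' @param params an [xv_params()]
#' @return tibble with node indices `i, j, k` (0-based, axes z, y, x) and
#'   node centre coordinates `z, y, x` (voxels); attributes `window`,
#'   `spacing`, `origin`, `nnodes`, `dim`
#' @examples
#' nrow(xv_grid(c(128, 128, 128), xv_params())) # 7^3 = 343
#' @export
xv_grid <- function(shape, params = xv_params()) {
  w <- params$window
  if (any(shape < w)) abort("window larger than the volume")
  step <- params$step
  nn <- pmax(1L, (shape - w) %/% step + 1L)
  origin <- (w - 1) / 2
  g <- expand.grid(i = 0:(nn[1] - 1), j = 0:(nn[2] - 1), k = 0:(nn[3] - 1))
  out <- tibble(
    i = g$i, j = g$j, k = g$k,
    z = origin + g$i * step, y = origin + g$j * step, x = origin + g$k * step
  )
  attr(out, "window") <- w
  attr(out, "spacing") <- step
  attr(out, "origin") <- origin
  attr(out, "nnodes") <- nn
  attr(out, "vol_dim") <- as.integer(shape)
  out
}

# subvoxel refinement along one axis from correlation samples (cm, c0, cp)
refine_peak1 <- function(cm, c0, cp, method) {
  if (!is.finite(cm) || !is.finite(cp)) return(0)
  if (method == "gaussian" && cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (den < 0) return(max(-1, min(1, (log(cm) - log(cp)) / den)))
  }
  den <- 2 * cm - 4 * c0 + 2 * cp
  if (den == 0) return(0)
  max(-1, min(1, (cm - cp) / den))
}

# masked, zero-padded (linear) normalised cross-correlation: statistics at
# every lag are computed over the overlap of the valid-voxel masks only, so
# strong structures outside the mask (chest wall, flat background) cannot
# bias the peak.  Lags are restricted to |k| <= window/4.
masked_ncc <- function(a, b, m, maxlag) {
  d <- dim(a)
  pdim <- d + 2L * maxlag
  pad <- function(x) {
    out <- array(0, pdim)
    out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
    out
  }
  a <- a - mean(a[m]); a[!m] <- 0
  b <- b - mean(b[m]); b[!m] <- 0
  Fm <- fft(pad(m + 0))
  Fa <- fft(pad(a)); Fb <- fft(pad(b))
  Fa2 <- fft(pad(a^2)); Fb2 <- fft(pad(b^2))
  n <- prod(pdim)
  xc <- function(X, Y) Re(fft(Conj(X) * Y, inverse = TRUE)) / n
  Nk <- xc(Fm, Fm)
  Sab <- xc(Fa, Fb)
  Sa <- xc(Fa, Fm); Sb <- xc(Fm, Fb)
  Saa <- xc(Fa2, Fm); Sbb <- xc(Fm, Fb2)
  num <- Sab - Sa * Sb / pmax(Nk, 1)
  va <- pmax(Saa - Sa^2 / pmax(Nk, 1), 0)
  vb <- pmax(Sbb - Sb^2 / pmax(Nk, 1), 0)
  cc <- num / sqrt(pmax(va * vb, 1e-300))
  nmin <- 0.2 * sum(m)
  lagmask <- function(np, nd) {
    k <- abs(fft_freq(np)) * np
    k <= min(maxlag, nd / 4)
  }
  keep <- outer(outer(lagmask(pdim[1], d[1]), lagmask(pdim[2], d[2]), `&`),
                lagmask(pdim[3], d[3]), `&`)
  cc[!keep | Nk < nmin] <- -Inf
  cc
}

#' Cross-correlate one window pair
#'
#' Normalised cross-correlation in the frequency domain.  The displacement
#' is the argmax of the correlation map refined to subvoxel precision by a
#' 3-point fit per axis; quality is the ratio of the primary to the
#' secondary correlation peak (secondary searched outside a 2-voxel
#' exclusion zone).  A zero-variance window yields an invalid flagged
#' result, not an error.  Displacements are searched over lags up to a
#' quarter of the window size.
#'
#' @param window_a,window_b equal-shaped numeric 3D arrays
#' @param refine `"gaussian"` or `"parabolic"` subvoxel estimator
#' @param normalize `"unbiased"` divides the correlation map by the
#'   triangular overlap factor, removing the systematic shrink of subvoxel
#'   displacements when windows are aperiodic views cut from a larger
#'   volume (the usual case); `"circular"` is the plain circular estimator,
#'   exact for periodically shifted windows
#' @param mask optional logical array marking the valid (e.g. lung) voxels
#'   of the windows; when given, a zero-padded masked normalised
#'   cross-correlation is used, with per-lag statistics over the mask
#'   overlap only, so structure outside the mask cannot bias the vector
#' @return list with `shift` (numeric `c(dz, dy, dx)`, the displacement of
#'   `window_b` relative to `window_a`), `peak_int` (integer peak),
#'   `quality` and `valid`
#' @export
correlate_pair <- function(window_a, window_b,
                           refine = c("gaussian", "parabolic"),
                           normalize = c("unbiased", "circular"),
                           mask = NULL) {
  refine <- match.arg(refine)
  normalize <- match.arg(normalize)
  if (!identical(dim(window_a), dim(window_b)))
    abort("windows must have equal shapes")
  d <- dim(window_a)
  use_mask <- !is.null(mask) && !all(mask)
  if (use_mask && sum(mask) < 27)
    return(list(shift = c(NA_real_, NA_real_, NA_real_),
                peak_int = c(NA_integer_, NA_integer_, NA_integer_),
                quality = 0, valid = FALSE))
  if (use_mask) {
    if (sd(window_a[mask]) == 0 || sd(window_b[mask]) == 0)
      return(list(shift = c(NA_real_, NA_real_, NA_real_),
                  peak_int = c(NA_integer_, NA_integer_, NA_integer_),
                  quality = 0, valid = FALSE))
    cc <- masked_ncc(window_a, window_b, mask, as.integer(min(d) %/% 4))
    dcc <- dim(cc)
  } else {
    a <- window_a - mean(window_a)
    b <- window_b - mean(window_b)
    sa <- sqrt(sum(a^2)); sb <- sqrt(sum(b^2))
    if (sa == 0 || sb == 0)
      return(list(shift = c(NA_real_, NA_real_, NA_real_),
                  peak_int = c(NA_integer_, NA_integer_, NA_integer_),
                  quality = 0, valid = FALSE))
    cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / (prod(d) * sa * sb)
    if (normalize == "unbiased") {
      # windows are aperiodic views of a larger scene, so the matched
      # content at lag k is attenuated by the triangular overlap factor
      # prod((N - |k|)/N); divide it out (displacements are restricted to
      # |k| <= N/4, where the correction is mild and stable)
      tri <- function(n) {
        k <- abs(fft_freq(n)) * n
        n / pmax(n - k, 1)
      }
      cc <- cc * outer(outer(tri(d[1]), tri(d[2]), `*`), tri(d[3]), `*`)
    }
    # search only physically meaningful lags (|k| <= N/4 per axis)
    lagmask <- function(n) abs(fft_freq(n)) * n <= n / 4
    keep <- outer(outer(lagmask(d[1]), lagmask(d[2]), `&`),
                  lagmask(d[3]), `&`)
    cc[!keep] <- -Inf
    dcc <- d
  }
  d <- dcc
  pk <- which.max(cc)
  pz <- (pk - 1) %% d[1]
  py <- ((pk - 1) %/% d[1]) %% d[2]
  px <- (pk - 1) %/% (d[1] * d[2])
  p1 <- cc[pk]
  # secondary peak outside a 2-voxel Chebyshev exclusion zone
  ez <- 2
  zi <- ((pz + (-ez:ez)) %% d[1]) + 1
  yi <- ((py + (-ez:ez)) %% d[2]) + 1
  xi <- ((px + (-ez:ez)) %% d[3]) + 1
  tmp <- cc
  tmp[zi, yi, xi] <- -Inf
  p2 <- max(tmp)
  quality <- if (p2 <= 0) Inf else p1 / p2
  at <- function(dz, dy, dx)
    cc[((pz + dz) %% d[1]) + 1, ((py + dy) %% d[2]) + 1,
       ((px + dx) %% d[3]) + 1]
  delta <- c(
    refine_peak1(at(-1, 0, 0), p1, at(1, 0, 0), refine),
    refine_peak1(at(0, -1, 0), p1, at(0, 1, 0), refine),
    refine_peak1(at(0, 0, -1), p1, at(0, 0, 1), refine)
  )
  ip <- c(pz, py, px)
  ip <- ifelse(ip > d / 2, ip - d, ip)
  list(shift = ip + delta, peak_int = as.integer(ip), quality = quality,
       valid = TRUE)
}

#' Displacement field between two volumes
#'
#' Runs [correlate_pair()] on every interrogation node of [xv_grid()].
#' Vectors with peak quality below `peak_quality_min`, from zero-variance
#' windows, or centred outside `lung_mask` are flagged invalid; invalid
#' interior nodes are (optionally) replaced by the component-wise median of
#' their valid 26-neighbours and flagged as replaced.
#'
#' @param vol_a,vol_b equal-shaped (pre-processed) volumes; the field maps
#'   `vol_a` towards `vol_b`
#' @param params an [xv_params()]
#' @param lung_mask optional logical array restricting valid nodes
#' @return an `xv_field`: tibble with node indices/coordinates, displacement
#'   components `u, v, w` (voxels, along z, y, x), `quality`, `valid`,
#'   `replaced`; grid metadata in attributes
#' @export
displacement_field <- function(vol_a, vol_b, params = xv_params(),
                               lung_mask = NULL) {
  assert_volume3(vol_a); assert_volume3(vol_b)
  if (!identical(dim(vol_a), dim(vol_b)))
    abort("volumes must have equal shapes")
  grid <- xv_grid(dim(vol_a), params)
  w <- attr(grid, "window")
  step <- attr(grid, "spacing")
  nn <- attr(grid, "nnodes")
  n <- nrow(grid)
  u <- v <- ww <- q <- numeric(n)
  mz <- grid$z; my <- grid$y; mx <- grid$x
  valid <- logical(n)
  in_mask <- rep(TRUE, n)
  if (!is.null(lung_mask))
    in_mask <- lung_mask[cbind(round(grid$z) + 1, round(grid$y) + 1,
                               round(grid$x) + 1)]
  for (r in seq_len(n)) {
    if (!in_mask[r]) { u[r] <- v[r] <- ww[r] <- NA_real_; next }
    z0 <- grid$i[r] * step + 1
    y0 <- grid$j[r] * step + 1
    x0 <- grid$k[r] * step + 1
    wa <- vol_a[z0:(z0 + w - 1), y0:(y0 + w - 1), x0:(x0 + w - 1)]
    wb <- vol_b[z0:(z0 + w - 1), y0:(y0 + w - 1), x0:(x0 + w - 1)]
    wm <- NULL
    if (!is.null(lung_mask)) {
      wm <- lung_mask[z0:(z0 + w - 1), y0:(y0 + w - 1), x0:(x0 + w - 1)]
      if (mean(wm) < 0.25) { u[r] <- v[r] <- ww[r] <- NA_real_; next }
      # a masked window measures the displacement of its lung content, so
      # the vector is located at the mask centroid, not the window centre
      idxm <- which(wm) - 1L
      mz[r] <- z0 - 1 + mean(idxm %% w)
      my[r] <- y0 - 1 + mean((idxm %/% w) %% w)
      mx[r] <- x0 - 1 + mean(idxm %/% (w * w))
    }
    res <- correlate_pair(wa, wb, refine = params$refine,
                          normalize = params$normalize, mask = wm)
    q[r] <- res$quality
    if (res$valid && res$quality >= params$peak_quality_min) {
      u[r] <- res$shift[1]; v[r] <- res$shift[2]; ww[r] <- res$shift[3]
      valid[r] <- TRUE
    } else {
      u[r] <- v[r] <- ww[r] <- NA_real_
    }
  }
  out <- dplyr::mutate(grid, mz = mz, my = my, mx = mx,
                       u = u, v = v, w = ww, quality = q,
                       valid = valid, replaced = FALSE)
  if (params$fill_invalid) out <- fill_invalid_nodes(out, nn)
  class(out) <- c("xv_field", class(out))
  for (a in c("window", "spacing", "origin", "nnodes", "vol_dim"))
    attr(out, a) <- attr(grid, a)
  attr(out, "params") <- params
  out
}

# median replacement of invalid interior nodes from valid 26-neighbours
fill_invalid_nodes <- function(field, nn) {
  bad <- which(!field$valid &
                 field$i > 0 & field$i < nn[1] - 1 &
                 field$j > 0 & field$j < nn[2] - 1 &
                 field$k > 0 & field$k < nn[3] - 1)
  if (!length(bad)) return(field)
  key <- field$i + nn[1] * (field$j + nn[2] * field$k)
  lookup <- match(seq_len(prod(nn)) - 1L, key)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  for (r in bad) {
    nb <- cbind(field$i[r] + off[, 1], field$j[r] + off[, 2],
                field$k[r] + off[, 3])
    rows <- lookup[nb[, 1] + nn[1] * (nb[, 2] + nn[2] * nb[, 3]) + 1L]
    rows <- rows[!is.na(rows)]
    rows <- rows[field$valid[rows]]
    if (length(rows) >= 3) {
      field$u[r] <- median(field$u[rows])
      field$v[r] <- median(field$v[rows])
      field$w[r] <- median(field$w[rows])
      field$replaced[r] <- TRUE
    }
  }
  field
}

#' Expansion (divergence) field of a displacement field
#'
#' Volumetric expansion per node as the divergence of the displacement,
#' computed by central differences on the interrogation grid (small-strain
#' first-order measure).  A node needs a full stencil of usable (valid or
#' replaced) neighbours along every axis; others are flagged invalid.
#'
#' @param field an `xv_field` from [displacement_field()]
#' @return an `xv_expansion`: tibble with node indices/coordinates,
#'   `expansion` (dimensionless) and `valid`
#' @export
expansion <- function(field) {
  nn <- attr(field, "nnodes")
  spacing <- attr(field, "spacing")
  if (any(nn < 3)) abort("expansion needs >= 3 nodes per axis")
  usable <- field$valid | field$replaced
  key <- field$i + nn[1] * (field$j + nn[2] * field$k)
  lookup <- match(seq_len(prod(nn)) - 1L, key)
  row_at <- function(i, j, k) {
    ok <- i >= 0 & i < nn[1] & j >= 0 & j < nn[2] & k >= 0 & k < nn[3]
    out <- rep(NA_integer_, length(i))
    out[ok] <- lookup[i[ok] + nn[1] * (j[ok] + nn[2] * k[ok]) + 1L]
    out
  }
  has_pos <- all(c("mz", "my", "mx") %in% names(field))
  pz <- if (has_pos) field$mz else field$z
  py <- if (has_pos) field$my else field$y
  px <- if (has_pos) field$mx else field$x
  # divergence by a local least-squares linear fit of the vectors over the
  # 6-neighbour stencil at the true measurement positions (equals central
  # differences on a regular grid; stays unbiased when masked boundary
  # windows localise their vectors at the lung-content centroid)
  n <- nrow(field)
  dvals <- rep(NA_real_, n)
  ez <- pz; ey <- py; exx <- px
  for (r in seq_len(n)) {
    nb <- c(row_at(field$i[r] + 1L, field$j[r], field$k[r]),
            row_at(field$i[r] - 1L, field$j[r], field$k[r]),
            row_at(field$i[r], field$j[r] + 1L, field$k[r]),
            row_at(field$i[r], field$j[r] - 1L, field$k[r]),
            row_at(field$i[r], field$j[r], field$k[r] + 1L),
            row_at(field$i[r], field$j[r], field$k[r] - 1L))
    if (anyNA(nb)) next
    if (!all(usable[nb]) || !usable[r]) next
    rows <- c(r, nb)
    X <- cbind(1, pz[rows] - pz[r], py[rows] - py[r], px[rows] - px[r])
    fit <- tryCatch(qr.coef(qr(X), cbind(field$u[rows], field$v[rows],
                                         field$w[rows])),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit[2:4, ])) next
    dvals[r] <- fit[2, 1] + fit[3, 2] + fit[4, 3]
    ez[r] <- mean(pz[rows]); ey[r] <- mean(py[rows]); exx[r] <- mean(px[rows])
  }
  # permissive companion estimate for quadrature: least-squares over all
  # usable vectors in the 27-neighbourhood, provided every axis has spread
  perm <- rep(NA_real_, n)
  pez <- pz; pey <- py; pex <- px
  for (r in seq_len(n)) {
    if (!is.na(dvals[r])) { perm[r] <- dvals[r]; next }
    nb <- which(abs(field$i - field$i[r]) <= 1 &
                  abs(field$j - field$j[r]) <= 1 &
                  abs(field$k - field$k[r]) <= 1 & usable)
    if (length(nb) < 10) next
    dzp <- pz[nb] - pz[r]; dyp <- py[nb] - py[r]; dxp <- px[nb] - px[r]
    if (diff(range(dzp)) < spacing / 2 || diff(range(dyp)) < spacing / 2 ||
        diff(range(dxp)) < spacing / 2) next
    X <- cbind(1, dzp, dyp, dxp)
    fit <- tryCatch(qr.coef(qr(X), cbind(field$u[nb], field$v[nb],
                                         field$w[nb])),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit[2:4, ])) next
    perm[r] <- fit[2, 1] + fit[3, 2] + fit[4, 3]
    pez[r] <- mean(pz[nb]); pey[r] <- mean(py[nb]); pex[r] <- mean(px[nb])
  }
  out <- tibble(
    i = field$i, j = field$j, k = field$k,
    z = field$z, y = field$y, x = field$x,
    ez = ez, ey = ey, ex = exx,
    pz = pez, py = pey, px = pex,
    expansion = dvals,
    expansion_ls = perm,
    valid = !is.na(dvals)
  )
  class(out) <- c("xv_expansion", class(out))
  attr(out, "nnodes") <- nn
  attr(out, "spacing") <- spacing
  attr(out, "window") <- attr(field, "window")
  attr(out, "vol_dim") <- attr(field, "vol_dim")
  attr(out, "field") <- field
  out
}

# trilinear interpolation of per-node values at fractional node coordinates
interp_field_nodes <- function(vals, usable, nn, fi, fj, fk) {
  n <- length(fi)
  out <- numeric(n)
  for (r in seq_len(n)) {
    i0 <- floor(fi[r]); j0 <- floor(fj[r]); k0 <- floor(fk[r])
    wsum <- 0; acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      i <- i0 + di; j <- j0 + dj; k <- k0 + dk
      if (i < 0 || i >= nn[1] || j < 0 || j >= nn[2] || k < 0 || k >= nn[3])
        next
      idx <- 1L + i + nn[1] * (j + nn[2] * k)
      if (!usable[idx]) next
      wgt <- (1 - abs(fi[r] - i)) * (1 - abs(fj[r] - j)) * (1 - abs(fk[r] - k))
      if (wgt <= 0) next
      acc <- acc + wgt * vals[idx]
      wsum <- wsum + wgt
    }
    out[r] <- if (wsum > 0) acc / wsum else NA_real_
  }
  out
}

#' Track lung motion across a breath series
#'
#' Pre-processes every phase, measures the displacement field between each
#' successive phase pair (`t -> t+1`, relative to the moving previous
#' phase), computes the per-interval expansion fields, and accumulates
#' displacement from phase 0 by summation with grid resampling along the
#' moving tissue trajectory.
#'
#' @param volume4d a [volume4d()] with >= 2 phases
#' @param params an [xv_params()]
#' @param lung_mask optional logical array
#' @return an object of class `xv_track`: list with `fields` (n-1
#'   `xv_field`s), `expansions` (n-1 `xv_expansion`s), `cumulative`
#'   (per-phase matrices of accumulated node displacement), `phase_times`
#'   and `params`
#' @export
track_breath <- function(volume4d, params = xv_params(), lung_mask = NULL) {
  if (!inherits(volume4d, "volume4d")) abort("`volume4d` must be a volume4d")
  nph <- n_phases(volume4d)
  if (nph < 2) abort("tracking needs >= 2 phases")
  pre <- lapply(volume4d$phases, xv_preprocess, params = params,
                lung_mask = lung_mask)
  fields <- vector("list", nph - 1)
  expansions <- vector("list", nph - 1)
  for (t in seq_len(nph - 1)) {
    fields[[t]] <- displacement_field(pre[[t]], pre[[t + 1]], params,
                                      lung_mask)
    expansions[[t]] <- expansion(fields[[t]])
  }
  # cumulative displacement from phase 0 at the phase-0 node positions
  f1 <- fields[[1]]
  nn <- attr(f1, "nnodes")
  spacing <- attr(f1, "spacing")
  nnode <- nrow(f1)
  cum <- vector("list", nph)
  cum[[1]] <- matrix(0, nnode, 3)
  key_order <- order(f1$k, f1$j, f1$i) # ensure i-fastest ordering
  for (t in seq_len(nph - 1)) {
    f <- fields[[t]]
    usable <- (f$valid | f$replaced)[key_order]
    uu <- f$u[key_order]; vv <- f$v[key_order]; wwv <- f$w[key_order]
    uu[!usable] <- 0; vv[!usable] <- 0; wwv[!usable] <- 0
    all_ok <- rep(TRUE, length(uu))
    fi <- f1$i + cum[[t]][, 1] / spacing
    fj <- f1$j + cum[[t]][, 2] / spacing
    fk <- f1$k + cum[[t]][, 3] / spacing
    du <- interp_field_nodes(uu, all_ok, nn, fi, fj, fk)
    dv <- interp_field_nodes(vv, all_ok, nn, fi, fj, fk)
    dw <- interp_field_nodes(wwv, all_ok, nn, fi, fj, fk)
    du[is.na(du)] <- 0; dv[is.na(dv)] <- 0; dw[is.na(dw)] <- 0
    cum[[t + 1]] <- cum[[t]] + cbind(du, dv, dw)
  }
  structure(
    list(fields = fields, expansions = expansions, cumulative = cum,
         phase_times = volume4d$phase_times, params = params),
    class = "xv_track"
  )
}

#' @export
print.xv_track <- function(x, ...) {
  cat(sprintf("<xv_track> %d interval fields on %d nodes\n",
              length(x$fields), nrow(x$fields[[1]])))
  invisible(x)
}

#' Cumulative nodal expansion across a tracked breath
#'
#' Sum of the per-interval expansion values at each node up to (and
#' including) interval `upto` — the small-strain cumulative volumetric
#' expansion relative to phase 0.
#'
#' @param track an [track_breath()] result
#' @param upto last interval to include (default all)
#' @return tibble of node coordinates with `expansion` and `valid`
#' @export
cumulative_expansion <- function(track, upto = length(track$expansions)) {
  ex <- track$expansions[seq_len(upto)]
  base <- ex[[1]]
  vals <- rowSums(do.call(cbind, lapply(ex, function(e) {
    v <- e$expansion
    v[is.na(v)] <- NA_real_
    v
  })))
  ok <- Reduce(`&`, lapply(ex, function(e) e$valid))
  out <- dplyr::mutate(base[, c("i", "j", "k", "z", "y", "x")],
                       expansion = vals, valid = ok)
  attr(out, "nnodes") <- attr(base, "nnodes")
  attr(out, "spacing") <- attr(base, "spacing")
  attr(out, "window") <- attr(base, "window")
  out
}
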