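# Internal numeric helpers shared across modules.

# DFT sample frequencies in cycles/sample (like numpy fftfreq)
fft_freq <- function(n) {
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2):1))
  k / n
}

# arrays of voxel indices (0-based) along each axis, shaped like `dim`
axis_grids <- function(dim) {
  nz <- dim[1]; ny <- dim[2]; nx <- dim[3]
  list(
    z = array(rep(seq_len(nz) - 1, times = ny * nx), dim = dim),
    y = array(rep(rep(seq_len(ny) - 1, each = nz), times = nx), dim = dim),
    x = array(rep(seq_len(nx) - 1, each = nz * ny), dim = dim)
  )
}

# |f| radial frequency array (cycles/voxel) for a 3D grid
radial_freq <- function(dim) {
  fz <- fft_freq(dim[1]); fy <- fft_freq(dim[2]); fx <- fft_freq(dim[3])
  fz2 <- array(rep(fz^2, times = dim[2] * dim[3]), dim = dim)
  fy2 <- array(rep(rep(fy^2, each = dim[1]), times = dim[3]), dim = dim)
  fx2 <- array(rep(fx^2, each = dim[1] * dim[2]), dim = dim)
  sqrt(fz2 + fy2 + fx2)
}

# Gaussian low-pass via FFT (periodic boundary); sigma in voxels
gaussian_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  f2 <- radial_freq(d)^2
  h <- exp(-2 * pi^2 * sigma^2 * f2)
  Re(fft(fft(vol) * h, inverse = TRUE)) / prod(d)
}

# Radial band-pass with raised-cosine edges of relative width `soft`
bandpass3 <- function(vol, band_low, band_high, soft = 0.2) {
  d <- dim(vol)
  f <- radial_freq(d)
  wlo <- band_low * soft + 1e-9
  whi <- band_high * soft + 1e-9
  ramp_up <- pmin(1, pmax(0, (f - (band_low - wlo)) / wlo))
  ramp_dn <- pmin(1, pmax(0, ((band_high + whi) - f) / whi))
  s <- function(t) t * t * (3 - 2 * t)
  h <- s(ramp_up) * s(ramp_dn)
  h[1] <- 0 # remove DC regardless
  Re(fft(fft(vol) * h, inverse = TRUE)) / prod(d)
}

# Scale-normalised Gaussian Hessian (gamma = 2) of a 3D volume via FFT.
# Returns the six independent components hzz, hyy, hxx, hzy, hzx, hyx.
gaussian_hessian3 <- function(vol, sigma) {
  d <- dim(vol)
  F0 <- fft(vol)
  fz <- fft_freq(d[1]); fy <- fft_freq(d[2]); fx <- fft_freq(d[3])
  gz <- array(rep(fz, times = d[2] * d[3]), dim = d)
  gy <- array(rep(rep(fy, each = d[1]), times = d[3]), dim = d)
  gx <- array(rep(fx, each = d[1] * d[2]), dim = d)
  G <- exp(-2 * pi^2 * sigma^2 * (gz^2 + gy^2 + gx^2))
  base <- F0 * G * (-(2 * pi)^2) * sigma^2 # gamma-normalisation sigma^2
  n <- prod(d)
  ift <- function(a) Re(fft(a, inverse = TRUE)) / n
  list(
    zz = ift(base * gz * gz), yy = ift(base * gy * gy),
    xx = ift(base * gx * gx), zy = ift(base * gz * gy),
    zx = ift(base * gz * gx), yx = ift(base * gy * gx)
  )
}

# Eigenvalues of many symmetric 3x3 matrices (vectorised trigonometric
# method), returned sorted by increasing |lambda| as a list l1, l2, l3.
eig3_sym <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-300
  ps <- ifelse(ok, p, 1)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # sort the triple by |value| with a 3-comparator network
  sw <- abs(e1) > abs(e2)
  t <- e1[sw]; e1[sw] <- e2[sw]; e2[sw] <- t
  sw <- abs(e2) > abs(e3)
  t <- e2[sw]; e2[sw] <- e3[sw]; e3[sw] <- t
  sw <- abs(e1) > abs(e2)
  t <- e1[sw]; e1[sw] <- e2[sw]; e2[sw] <- t
  list(l1 = e1, l2 = e2, l3 = e3)
}

# Otsu's threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1000003) %% 2147483647)
}

# circular shift of a 3D array by integer offsets (z, y, x)
circ_shift3 <- function(vol, shift) {
  d <- dim(vol)
  idx <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  vol[idx(d[1], shift[1]), idx(d[2], shift[2]), idx(d[3], shift[3])]
}

# subvoxel shift of a 3D array via a Fourier phase ramp (periodic)
fourier_shift3 <- function(vol, shift) {
  d <- dim(vol)
  fz <- fft_freq(d[1]); fy <- fft_freq(d[2]); fx <- fft_freq(d[3])
  gz <- array(rep(fz, times = d[2] * d[3]), dim = d)
  gy <- array(rep(rep(fy, each = d[1]), times = d[3]), dim = d)
  gx <- array(rep(fx, each = d[1] * d[2]), dim = d)
  ph <- exp(-2i * pi * (gz * shift[1] + gy * shift[2] + gx * shift[3]))
  Re(fft(fft(vol) * ph, inverse = TRUE)) / prod(d)
}

assert_volume3 <- function(vol, what = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3 || !is.numeric(vol))
    abort(sprintf("`%s` must be a numeric 3D array", what))
  invisible(vol)
}
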