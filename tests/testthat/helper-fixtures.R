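# Shared fixtures, built once per test run and cached (several tests reuse
# the same simulated breath series and tracked fields).

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env))
    assign(name, build(), envir = fixture_env)
  get(name, envir = fixture_env)
}

# default study phantom (96^3, 6 generations, 15 phases), noise-free
phantom_clean <- function() {
  fixture("phantom_clean", function()
    simulate_breath_series(phantom_spec(noise_sigma = 0)))
}

# XV tracking of the default phantom
track_clean <- function() {
  fixture("track_clean", function()
    track_breath(phantom_clean()$volumes, xv_params(),
                 phantom_clean()$lung_mask))
}

# generation-6 phantom with a slow-emptying regional defect (tau x2)
phantom_defect <- function() {
  fixture("phantom_defect", function()
    simulate_breath_series(phantom_spec(
      noise_sigma = 0,
      defects = list(defect_spec(center = c(55, 28, 47.5), radius = 22,
                                 expansion_scale = 0.6, tau_scale = 2,
                                 support = "regions")))))
}

# band-limited random speckle volume
speckle_volume <- function(dim, sigma = 1.5, seed = 1) {
  set.seed(seed)
  gaussian_smooth3_ <- getFromNamespace("gaussian_smooth3", "lung4dxv")
  gaussian_smooth3_(array(rnorm(prod(dim)), dim), sigma)
}

circ_shift3_ <- function(...) {
  getFromNamespace("circ_shift3", "lung4dxv")(...)
}

fourier_shift3_ <- function(...) {
  getFromNamespace("fourier_shift3", "lung4dxv")(...)
}

axis_grids_ <- function(...) {
  getFromNamespace("axis_grids", "lung4dxv")(...)
}

warp_volume_ <- function(vol, uz, uy, ux, order = 3) {
  getFromNamespace("cpp_warp_volume", "lung4dxv")(
    vol, dim(vol), uz, uy, ux, order)
}

# paint a capsule (cylinder with round caps) into a logical volume
paint_capsule <- function(m, p0, p1, r) {
  d <- dim(m)
  n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2))) * 2L)
  for (t in seq(0, 1, length.out = n)) {
    p <- p0 + t * (p1 - p0)
    zr <- max(0, floor(p[1] - r)):min(d[1] - 1, ceiling(p[1] + r))
    yr <- max(0, floor(p[2] - r)):min(d[2] - 1, ceiling(p[2] + r))
    xr <- max(0, floor(p[3] - r)):min(d[3] - 1, ceiling(p[3] + r))
    ball <- outer(outer((zr - p[1])^2, (yr - p[2])^2, `+`),
                  (xr - p[3])^2, `+`) <= r^2
    m[zr + 1, yr + 1, xr + 1] <- m[zr + 1, yr + 1, xr + 1] | ball
  }
  m
}

# a displacement field tibble with analytically prescribed vectors
prescribe_field <- function(field, fu, fv, fw) {
  field$u <- fu(field$z, field$y, field$x)
  field$v <- fv(field$z, field$y, field$x)
  field$w <- fw(field$z, field$y, field$x)
  field$valid <- TRUE
  field$replaced <- FALSE
  field
}
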