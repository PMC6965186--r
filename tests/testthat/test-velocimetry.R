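test_that("preprocessing removes DC and confines power to the pass band", {
  p <- xv_params(band_low = 0.05, band_high = 0.2)
  # constant volume -> all-zero output (DC removed)
  out <- xv_preprocess(array(3.7, c(32, 32, 32)), p)
  expect_equal(max(abs(out)), 0, tolerance = 1e-12)
  # white noise: power strictly outside the (soft-edged) band vanishes
  set.seed(21)
  wn <- array(rnorm(48^3), c(48, 48, 48))
  filt <- xv_preprocess(wn, p)
  f <- getFromNamespace("radial_freq", "lung4dxv")(dim(filt))
  spec_power <- Mod(fft(filt))^2
  outside <- f < p$band_low * 0.7 | f > p$band_high * 1.3
  expect_lt(sum(spec_power[outside]) / sum(spec_power), 0.01)
  # Nyquist guard
  expect_error(xv_preprocess(wn, xv_params(band_high = 0.6)), "Nyquist")
})

test_that("the default band retains most of the phantom speckle power", {
  ph <- phantom_clean()
  p <- xv_params()
  v <- ph$reference
  pre <- xv_preprocess(v, p, ph$lung_mask)
  raw <- v - mean(v[ph$lung_mask])
  raw[!ph$lung_mask] <- 0
  expect_gt(sum(pre^2) / sum(raw^2), 0.5)
})

test_that("interrogation grids step by window * (1 - overlap)", {
  g <- xv_grid(c(128, 128, 128), xv_params())
  expect_equal(nrow(g), 343)
  expect_equal(attr(g, "nnodes"), c(7L, 7L, 7L))
  expect_equal(attr(g, "spacing"), 16L)
  g0 <- xv_grid(c(128, 128, 128), xv_params(overlap = 0))
  expect_equal(attr(g0, "nnodes"), c(4L, 4L, 4L))
  g1 <- xv_grid(c(32, 32, 32), xv_params())
  expect_equal(nrow(g1), 1)
  expect_error(xv_grid(c(16, 16, 16), xv_params()), "window larger")
})

test_that("window correlation recovers shifts and flags degenerate input", {
  a <- speckle_volume(c(32, 32, 32), 1.5, seed = 1)
  # periodic shifts are exact under the circular estimator
  b <- circ_shift3_(a, c(3, -2, 1))
  r <- correlate_pair(a, b, normalize = "circular")
  expect_equal(r$shift, c(3, -2, 1), tolerance = 1e-9)
  expect_equal(r$peak_int, c(3L, -2L, 1L))
  # identical windows: zero shift, quality above 1
  r0 <- correlate_pair(a, a)
  expect_equal(r0$shift, c(0, 0, 0), tolerance = 1e-9)
  expect_gt(r0$quality, 1)
  # subvoxel periodic shift
  r5 <- correlate_pair(a, fourier_shift3_(a, c(0.5, 0, 0)),
                       normalize = "circular")
  expect_lt(max(abs(r5$shift - c(0.5, 0, 0))), 0.05)
  # zero-variance window: invalid flag, no exception
  rz <- correlate_pair(array(1, c(16, 16, 16)), a[1:16, 1:16, 1:16])
  expect_false(rz$valid)
  expect_equal(rz$quality, 0)
  expect_error(correlate_pair(a, a[1:16, 1:16, 1:16]), "equal shapes")
})

test_that("masked correlation ignores structure outside the mask", {
  sp <- speckle_volume(c(64, 64, 64), 1.8, seed = 5)
  spb <- fourier_shift3_(sp, c(0.3, 0.2, 0))
  # bury a strong static (non-moving) block outside the mask
  spb2 <- spb
  sp2 <- sp
  sp2[17:48, 33:48, 17:48] <- 5
  spb2[17:48, 33:48, 17:48] <- 5
  wa <- sp2[17:48, 17:48, 17:48]
  wb <- spb2[17:48, 17:48, 17:48]
  m <- array(TRUE, c(32, 32, 32))
  m[, 17:32, ] <- FALSE
  r <- correlate_pair(wa, wb, mask = m)
  expect_lt(max(abs(r$shift - c(0.3, 0.2, 0))), 0.1)
})

test_that("volume-level fields recover global shifts at every valid node", {
  vol <- speckle_volume(c(96, 96, 96), 1.5, seed = 2)
  p <- xv_params()
  f <- displacement_field(vol, circ_shift3_(vol, c(2, 0, -3)), p)
  expect_true(all(f$valid))
  expect_true(all(round(f$u) == 2 & round(f$v) == 0 & round(f$w) == -3))
  expect_lt(max(abs(f$u - 2), abs(f$v), abs(f$w + 3)), 0.2)
  # static volume: zero field
  f0 <- displacement_field(vol, vol, p)
  expect_lt(max(abs(c(f0$u, f0$v, f0$w))), 1e-6)
})

test_that("low-quality regions are invalidated and interior gaps filled", {
  vol <- speckle_volume(c(64, 64, 64), 1.5, seed = 9)
  volb <- vol
  set.seed(10)
  volb[1:32, , ] <- array(rnorm(32 * 64 * 64), c(32, 64, 64))
  f <- displacement_field(vol, volb, xv_params(fill_invalid = FALSE))
  # windows fully inside the decorrelated half lose their peak ratio
  expect_true(all(!f$valid[f$z <= 16]))
  expect_true(all(f$valid[f$z >= 40]))
  # median replacement flags interior nodes it fills
  fr <- displacement_field(vol, volb, xv_params())
  expect_true(all(fr$replaced[fr$replaced] | !fr$valid[fr$replaced]))
  expect_gte(sum(fr$replaced), 0)
})

test_that("vectors respect the lung mask", {
  vol <- speckle_volume(c(64, 64, 64), 1.5, seed = 3)
  mask <- array(FALSE, dim(vol))
  mask[, , 33:64] <- TRUE
  f <- displacement_field(vol, circ_shift3_(vol, c(1, 0, 0)),
                          xv_params(), mask)
  outside <- round(f$x) < 32
  expect_true(all(!f$valid[outside]))
  expect_true(any(f$valid[!outside]))
})

test_that("added noise never raises the median peak quality", {
  vol <- speckle_volume(c(64, 64, 64), 1.5, seed = 9)
  meds <- vapply(c(0, 1, 3), function(s) {
    set.seed(11)
    vb <- vol + array(rnorm(length(vol), 0, s * sd(vol)), dim(vol))
    f <- displacement_field(vol, vb, xv_params(peak_quality_min = 0))
    median(f$quality)
  }, 0)
  expect_true(all(diff(meds) <= 1e-9))
})

test_that("expansion equals the analytic divergence on prescribed fields", {
  p <- xv_params()
  grid <- displacement_field(speckle_volume(c(96, 96, 96), 1.5, seed = 2),
                             speckle_volume(c(96, 96, 96), 1.5, seed = 2),
                             p)
  ctr <- 47.5
  # zero field -> zero expansion
  f0 <- prescribe_field(grid, function(z, y, x) 0 * z,
                        function(z, y, x) 0 * y, function(z, y, x) 0 * x)
  e0 <- expansion(f0)
  expect_equal(max(abs(e0$expansion[e0$valid])), 0, tolerance = 1e-12)
  # linear dilation 0.01 per axis -> divergence exactly 0.03 at all
  # interior nodes
  fl <- prescribe_field(grid,
                        function(z, y, x) 0.01 * (z - ctr),
                        function(z, y, x) 0.01 * (y - ctr),
                        function(z, y, x) 0.01 * (x - ctr))
  el <- expansion(fl)
  expect_true(any(el$valid))
  expect_equal(max(abs(el$expansion[el$valid] - 0.03)), 0,
               tolerance = 1e-12)
  # too-small grids are rejected
  small <- displacement_field(speckle_volume(c(32, 32, 32), 1.5, seed = 2),
                              speckle_volume(c(32, 32, 32), 1.5, seed = 2),
                              p)
  expect_error(expansion(small), ">= 3 nodes")
})

test_that("breath tracking produces one field per interval, zero for a
           static series", {
  vol <- speckle_volume(c(64, 64, 64), 1.5, seed = 13)
  v4 <- volume4d(list(vol, vol, vol, vol), phase_times = (0:3) * 100)
  tr <- track_breath(v4, xv_params())
  expect_length(tr$fields, 3)
  expect_length(tr$expansions, 3)
  for (f in tr$fields)
    expect_lt(max(abs(c(f$u, f$v, f$w))), 1e-6)
  expect_equal(max(abs(tr$cumulative[[4]])), 0, tolerance = 1e-6)
  expect_error(track_breath(volume4d(list(vol)), xv_params()),
               ">= 2 phases")
})

test_that("cumulative phantom expansion aggregates to the closed-form
           regional volumes", {
  # pointwise nodal expansion maps are noisy relative to their spatial
  # contrast at this problem size; the scientifically used quantity is the
  # region-aggregated expansion, which must track the closed form tightly
  ph <- phantom_clean()
  track <- track_clean()
  labels <- assign_regions(ph$lung_mask, ph$tree)
  reg <- regional_volumes(track$expansions, labels, track$phase_times,
                          ph$spec$voxel_size, lung_mask = ph$lung_mask)
  tp <- which.max(ph$truth$total$volume) - 1
  m <- merge(reg[reg$phase == tp, ],
             ph$truth$regional_volumes[ph$truth$regional_volumes$phase == tp, ],
             by = "id")
  expect_gt(cor(m$volume.x, m$volume.y), 0.95)
})
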