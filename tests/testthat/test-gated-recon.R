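test_that("gating arithmetic matches the ventilator trigger", {
  expect_equal(phases_per_breath(gating_schedule(30, 120)), 15)
  expect_equal(phases_per_breath(gating_schedule(30, 60)), 30)
  expect_error(gating_schedule(30, 70), "drift")
})

test_that("effective pixel size is the demagnified detector pitch", {
  g <- recon_geometry(r1 = 0.36, r2 = 3.0, detector_pitch = 194e-6)
  expect_equal(effective_pixel_size(g), 194e-6 * 0.36 / 3.0)
  expect_equal(round(effective_pixel_size(g) * 1e6, 1), 23.3)
  g2 <- recon_geometry(r1 = 1, r2 = 1 + 1e-9, detector_pitch = 1e-4)
  expect_equal(effective_pixel_size(g2), 1e-4, tolerance = 1e-6)
  g3 <- recon_geometry(r1 = 0.5, r2 = 1.0, detector_pitch = 100e-6)
  expect_equal(effective_pixel_size(g3), 50e-6)
  expect_error(recon_geometry(r1 = 2, r2 = 1), "r1 < r2")
})

test_that("binning is a partition with equal counts over whole breaths", {
  sched <- gating_schedule(30, 120)
  make_set <- function(n) {
    projection_set(array(seq_len(4 * n), c(2, 2, n)),
                   angles = (seq_len(n) - 1) * 360 / n,
                   phase_tags = (seq_len(n) - 1) %% 15)
  }
  for (n in c(6000, 15, 7200)) {
    ps <- make_set(n)
    bins <- bin_projections_by_phase(ps, sched)
    counts <- vapply(bins, function(b) dim(b$images)[3], 0L)
    expect_equal(counts, rep(n / 15, 15))
    # every projection lands in exactly one bin, angles preserved
    expect_equal(sort(unlist(lapply(bins, `[[`, "angles"))),
                 sort(ps$angles))
    for (b in bins) expect_length(unique(b$phase_tags), 1)
  }
  # missing phases are reported
  ps <- make_set(30)
  ps$phase_tags[ps$phase_tags == 7] <- 8L
  expect_error(bin_projections_by_phase(ps, sched), "phase bin")
})

test_that("FDK is linear, zero-preserving, and centers an impulse", {
  geom <- recon_geometry(detector_shape = c(64, 64))
  angles <- (0:49) * 360 / 50
  imp <- array(0, c(32, 32, 32))
  imp[16, 16, 16] <- 1
  ps <- forward_project(imp, geom, angles)
  rec <- fdk_reconstruct(ps, geom, c(32, 32, 32))
  expect_equal(which(rec == max(rec)),
               16L + 32L * 15L + 32L * 32L * 15L)
  ps2 <- ps
  ps2$images <- 3 * ps$images
  rec2 <- fdk_reconstruct(ps2, geom, c(32, 32, 32))
  expect_equal(rec2, 3 * rec, tolerance = 1e-12)
  ps0 <- ps
  ps0$images[] <- 0
  expect_equal(max(abs(fdk_reconstruct(ps0, geom, c(32, 32, 32)))), 0)
  expect_error(fdk_reconstruct(list(), geom, c(32, 32, 32)), "projection")
})

test_that("projections of a centered sphere are rotation-invariant", {
  geom <- recon_geometry(detector_shape = c(96, 96))
  g <- axis_grids_(c(64, 64, 64))
  r <- sqrt((g$z - 31.5)^2 + (g$y - 31.5)^2 + (g$x - 31.5)^2)
  sph <- array(pmin(1, pmax(0, 16 - r)), c(64, 64, 64))
  ps <- forward_project(sph, geom, c(0, 137.5))
  expect_lt(max(abs(ps$images[, , 1] - ps$images[, , 2])) /
              max(ps$images), 0.05)
})

test_that("reconstruction quality is non-decreasing in angular sampling", {
  geom <- recon_geometry(detector_shape = c(96, 96))
  g <- axis_grids_(c(48, 48, 48))
  r <- sqrt((g$z - 23.5)^2 + (g$y - 23.5)^2 + (g$x - 23.5)^2)
  sph <- array(pmin(1, pmax(0, 12 - r)), c(48, 48, 48))
  cors <- vapply(c(10, 40, 120), function(na) {
    ps <- forward_project(sph, geom, (seq_len(na) - 1) * 360 / na)
    cor(as.numeric(fdk_reconstruct(ps, geom, c(48, 48, 48))),
        as.numeric(sph))
  }, 0)
  expect_true(all(diff(cors) >= 0))
})

test_that("a gated 4D set reconstructs phase volumes in time order", {
  # identical projections in every phase give identical phase volumes
  geom <- recon_geometry(detector_shape = c(48, 48))
  sched <- gating_schedule(30, 120)
  g <- axis_grids_(c(32, 32, 32))
  r <- sqrt((g$z - 15.5)^2 + (g$y - 15.5)^2 + (g$x - 15.5)^2)
  sph <- array(pmin(1, pmax(0, 8 - r)), c(32, 32, 32))
  nfr <- 15 * 40
  angles <- (seq_len(nfr) - 1) * 360 / nfr
  static <- volume4d(replicate(15, sph, simplify = FALSE),
                     phase_times = (0:14) * 500 / 15)
  ps <- forward_project(static, geom, angles, sched)
  v4 <- reconstruct_4d(ps, sched, geom, c(32, 32, 32))
  expect_equal(n_phases(v4), 15)
  expect_equal(v4$phase_times, (0:14) * 500 / 15)
  base <- as.numeric(v4$phases[[1]])
  for (i in c(5, 11))
    expect_gt(cor(base, as.numeric(v4$phases[[i]])), 0.99)
})
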