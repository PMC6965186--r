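test_that("ventilation protocol enforces breath-period consistency", {
  p <- ventilation_protocol()
  expect_equal(p$t_insp + p$t_exp, 60000 / p$respiratory_rate)
  expect_error(ventilation_protocol(t_insp = 200, t_exp = 200),
               "60000 / respiratory_rate")
  expect_error(ventilation_protocol(pip = -1), "> 0")
  expect_equal(breaths_per_minute(250, 250), 120)
  expect_equal(breaths_per_minute(150, 350), 120)
})

test_that("phantom spec validates its invariants", {
  expect_error(phantom_spec(n_phases = 1), "n_phases")
  expect_error(phantom_spec(tidal_fraction = 0.7), "tidal_fraction")
  expect_error(phantom_spec(tree_generations = -1), "tree_generations")
  expect_error(defect_spec(c(1, 1, 1), 5, expansion_scale = 1.2),
               "expansion_scale")
  expect_error(defect_spec(c(1, 1, 1), 5, tau_scale = 0.5), "tau_scale")
})

test_that("airway tree generation yields full binary trees", {
  # 2^(g+1)-1 segments, 2^g terminals, radii strictly decreasing
  for (g in c(0L, 3L, 6L)) {
    spec <- phantom_spec(grid_shape = c(96, 96, 96), tree_generations = g)
    tr <- generate_airway_tree(spec)
    gl <- glance(tr)
    expect_equal(gl$n_segments, 2^(g + 1) - 1)
    expect_equal(gl$n_terminals, 2^g)
    expect_equal(gl$max_generation, g)
    td <- tidy(tr)
    expect_true(all(td$generation[td$terminal] == g))
  }
  # graph traversal: edge count and generation = bifurcation depth
  skip_if_not_installed("igraph")
  tr <- generate_airway_tree(phantom_spec(tree_generations = 4))
  s <- tr$segments
  edges <- cbind(as.character(s$parent_id[!is.na(s$parent_id)]),
                 as.character(s$id[!is.na(s$parent_id)]))
  gr <- igraph::graph_from_edgelist(edges)
  expect_equal(igraph::ecount(gr), nrow(s) - 1)
  dists <- igraph::distances(gr, v = as.character(tr$root_id),
                             mode = "out")
  expect_equal(as.numeric(dists[1, as.character(s$id)]),
               as.numeric(s$generation))
})

test_that("trees that do not fit the grid raise a named error", {
  expect_error(generate_airway_tree(phantom_spec(grid_shape = c(24, 24, 24),
                                                 tree_generations = 10)),
               "exceeds grid bounds at segment")
})

test_that("reference rendering is deterministic with dark lumens and the
           prescribed speckle grain", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), tree_generations = 2,
                       noise_sigma = 0)
  tr <- generate_airway_tree(spec)
  reg <- phantom_regions(tr, spec)
  v1 <- render_reference_volume(tr, spec, reg)
  v2 <- render_reference_volume(tr, spec, reg)
  expect_identical(v1, v2)
  expect_lt(mean(v1[reg$lumen_mask]), mean(v1[reg$lung_mask]))
  # autocorrelation FWHM of the parenchyma texture ~ speckle_grain +- 50%
  v <- v1 - mean(v1[reg$lung_mask])
  v[!reg$lung_mask] <- 0
  ac <- Re(fft(Mod(fft(v))^2, inverse = TRUE))
  prof <- ac[1:10, 1, 1] / ac[1, 1, 1]
  fwhm <- 2 * approx(prof, 0:9, xout = 0.5)$y
  expect_gt(fwhm, 0.5 * spec$speckle_grain)
  expect_lt(fwhm, 1.5 * spec$speckle_grain)
})

test_that("analytic displacement is zero at end-expiration and matches the
           closed-form divergence", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), tree_generations = 2,
                       center_taper = 0, noise_sigma = 0)
  m <- phantom_motion(spec)
  u0 <- m$displacement(0)
  expect_equal(max(abs(u0$uz)), 0)
  expect_equal(max(abs(u0$uy)), 0)
  expect_equal(max(abs(u0$ux)), 0)
  expect_equal(max(abs(m$divergence(0))), 0)
  # with no taper the field at peak is a uniform dilation a*(x - c):
  # divergence is exactly 3a everywhere
  a <- spec$tidal_fraction / 3
  dv <- m$divergence(spec$ventilation$t_insp)
  expect_equal(max(abs(dv - 3 * a)), 0, tolerance = 1e-12)
  expect_error(m$displacement(600), "outside breath period")
})

test_that("a spherical defect scales the local divergence by its
           expansion_scale", {
  ctr <- c(47.5, 47.5, 47.5)
  spec <- phantom_spec(
    grid_shape = c(96, 96, 96), tree_generations = 2, noise_sigma = 0,
    defects = list(defect_spec(center = c(47.5, 47.5, 67.5), radius = 12,
                               expansion_scale = 0.5)))
  m <- phantom_motion(spec)
  dv <- m$divergence(spec$ventilation$t_insp)
  # mirrored points at the same lung radius, inside vs outside the defect
  inside <- dv[48, 48, 68]   # 0-based (47, 47, 67), deep in the defect
  outside <- dv[48, 48, 29]  # mirrored about the lung centre, same radius
  expect_equal(inside / outside, 0.5, tolerance = 1e-6)
})

test_that("simulated breath series anchors phase 0 and conserves regional
           ground truth", {
  spec <- phantom_spec(grid_shape = c(48, 48, 48), tree_generations = 2,
                       n_phases = 6, noise_sigma = 0)
  ph <- simulate_breath_series(spec)
  expect_identical(ph$volumes$phases[[1]], ph$reference)
  # phase times span [0, period)
  expect_equal(ph$volumes$phase_times,
               seq(0, 500, length.out = 7)[1:6])
  # regional ground truth sums to the total at every phase
  sums <- tapply(ph$truth$regional_volumes$volume,
                 ph$truth$regional_volumes$phase, sum)
  expect_equal(as.numeric(sums), ph$truth$total$volume, tolerance = 1e-9)
  # determinism
  ph2 <- simulate_breath_series(spec)
  expect_identical(ph$volumes$phases, ph2$volumes$phases)
})

test_that("zero tidal fraction freezes the breath", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), tree_generations = 1,
                       n_phases = 4, noise_sigma = 0, tidal_fraction = 1e-9)
  ph <- simulate_breath_series(spec)
  for (i in 2:4)
    expect_equal(ph$volumes$phases[[i]], ph$volumes$phases[[1]],
                 tolerance = 1e-6)
})

test_that("phase tags cycle with the gating period during acquisition", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), tree_generations = 1,
                       n_phases = 15, noise_sigma = 0)
  ph <- simulate_breath_series(spec)
  geom <- recon_geometry(detector_shape = c(48, 48))
  sched <- gating_schedule(30, 120)
  angles <- (0:44) * 8
  ps <- forward_project(ph$volumes, geom, angles, sched)
  expect_equal(ps$phase_tags, rep(0:14, 3))
  # empty volume projects to zero
  z4 <- volume4d(replicate(15, array(0, c(32, 32, 32)), simplify = FALSE),
                 phase_times = ph$volumes$phase_times)
  ps0 <- forward_project(z4, geom, angles, sched)
  expect_equal(max(abs(ps0$images)), 0)
})
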