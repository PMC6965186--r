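test_that("tubularity responds to tubes, not plates or constants", {
  d <- c(48, 48, 48)
  g <- axis_grids_(d)
  r2d <- sqrt((g$y - 23.5)^2 + (g$x - 23.5)^2)
  cyl <- array(1, d); cyl[r2d <= 4] <- 0
  plate <- array(1, d); plate[abs(g$x - 23.5) <= 4] <- 0
  p <- vesselness_params(scales = c(2, 3, 4, 5, 6))
  tc <- multiscale_tubularity(cyl, p)
  tp <- multiscale_tubularity(plate, p)
  expect_true(all(tc$response >= 0 & tc$response <= 1))
  cyl_med <- median(tc$response[r2d < 0.8])
  plate_med <- median(tp$response[abs(g$x - 23.5) < 0.8])
  expect_gte(cyl_med, 2 * max(plate_med, 0.05))
  # response maximal on the centerline vs one radius off-axis
  off_med <- median(tc$response[abs(r2d - 4) < 0.5])
  expect_gt(cyl_med, off_med)
  # constant volume: zero Hessian, zero response
  t0 <- multiscale_tubularity(array(0.7, c(24, 24, 24)),
                              vesselness_params(scales = c(2, 4)))
  expect_equal(max(t0$response), 0)
  # volume smaller than kernel support errors
  expect_error(multiscale_tubularity(array(0, c(16, 16, 16)),
                                     vesselness_params(scales = c(1, 30))),
               "kernel support")
})

test_that("tubularity is offset-invariant and monotone in contrast", {
  d <- c(32, 32, 32)
  g <- axis_grids_(d)
  r2d <- sqrt((g$y - 15.5)^2 + (g$x - 15.5)^2)
  p <- vesselness_params(scales = c(2, 3, 4))
  base <- array(1, d); base[r2d <= 3] <- 0.5
  t1 <- multiscale_tubularity(base, p)
  t2 <- multiscale_tubularity(base + 5, p)
  expect_equal(t1$response, t2$response, tolerance = 1e-8)
  strong <- array(1, d); strong[r2d <= 3] <- 0
  t3 <- multiscale_tubularity(strong, p)
  expect_gte(median(t3$response[r2d < 1]), median(t1$response[r2d < 1]))
})

test_that("flood fill keeps only the seeded component", {
  d <- c(40, 40, 40)
  g <- axis_grids_(d)
  two <- array(0, d)
  two[sqrt((g$y - 10)^2 + (g$x - 10)^2) <= 3] <- 1
  two[sqrt((g$y - 30)^2 + (g$x - 30)^2) <= 3] <- 1
  mask <- flood_fill_segment(two, c(20, 10, 10), threshold = 0.5)
  expect_true(mask[21, 11, 11])
  expect_false(any(mask[, 25:40, 25:40]))
  # threshold 0 floods the entire support reachable from the seed
  m2 <- flood_fill_segment(two + 1e-6, c(20, 10, 10), threshold = 0)
  expect_equal(sum(m2), prod(d))
  expect_error(flood_fill_segment(two, c(20, 20, 20), threshold = 0.5),
               "below threshold")
})

test_that("skeletonization recovers cylinder and Y-junction topology", {
  d <- c(48, 48, 48)
  cyl <- paint_capsule(array(FALSE, d), c(2, 24, 24), c(45, 24, 24), 3.5)
  tr <- skeletonize_to_tree(cyl, c(2, 24, 24))
  expect_equal(glance(tr)$n_segments, 1)
  expect_equal(glance(tr)$n_bifurcations, 0)
  expect_equal(tr$segments$generation, 0L)

  Y <- array(FALSE, d)
  Y <- paint_capsule(Y, c(2, 24, 24), c(22, 24, 24), 3.5)
  Y <- paint_capsule(Y, c(22, 24, 24), c(42, 36, 24), 3)
  Y <- paint_capsule(Y, c(22, 24, 24), c(42, 12, 24), 3)
  trY <- skeletonize_to_tree(Y, c(2, 24, 24))
  expect_equal(glance(trY)$n_segments, 3)
  expect_equal(glance(trY)$n_bifurcations, 1)
  expect_equal(sort(trY$segments$generation), c(0L, 1L, 1L))
  # segment graph is a tree: |edges| = |nodes| - 1
  expect_equal(sum(!is.na(trY$segments$parent_id)),
               nrow(trY$segments) - 1)
  # disconnected masks are rejected
  two <- cyl
  two[30:40, 5:10, 5:10] <- TRUE
  expect_error(skeletonize_to_tree(two, c(2, 24, 24)), "disconnected")
})

test_that("the airway chain recovers a rendered phantom tree", {
  spec <- phantom_spec(grid_shape = c(96, 96, 96), tree_generations = 3,
                       n_phases = 2, noise_sigma = 0)
  ph <- simulate_breath_series(spec)
  rt <- round(ph$tree$segments$points[[1]][2, 1:3])
  p <- vesselness_params(scales = c(1.4, 2, 2.8, 3.8, 5))
  tub <- multiscale_tubularity(ph$volumes$phases[[1]], p)
  mask <- flood_fill_segment(tub, rt)
  # flood fill recovers most of the upper-generation lumen
  lum <- ph$lumen_mask
  expect_gt(sum(mask & lum) / sum(lum), 0.6)
  tr <- skeletonize_to_tree(mask, rt)
  gl <- glance(tr)
  expect_equal(gl$n_segments, 15)
  expect_equal(gl$n_terminals, 8)
  expect_equal(gl$max_generation, 3)
  # segment_airways uses phase 0 only: permuting later phases changes nothing
  v4 <- ph$volumes
  v4$phases <- list(v4$phases[[1]], v4$phases[[2]])
  tr2 <- segment_airways(v4, p, rt)
  expect_equal(glance(tr2), gl)
  # pure-noise input fails with a degenerate-input error
  set.seed(4)
  noise <- array(rnorm(64^3, 0.5, 0.05), c(64, 64, 64))
  expect_error(
    segment_airways(noise, vesselness_params(scales = c(1.5, 2.5)),
                    c(32, 32, 32)),
    "too small|below threshold")
})
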