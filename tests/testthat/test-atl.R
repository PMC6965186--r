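mini_tree <- function(ends) {
  # a root plus one generation of terminals at the given endpoints
  n <- nrow(ends)
  if (n == 1) {
    segs <- tibble::tibble(
      id = 1L, parent_id = NA_integer_, generation = 0L,
      points = list(cbind(c(ends$z[1] - 5, ends$z[1]),
                          ends$y[1], ends$x[1], 2)))
    return(airway_tree(segs, 1L))
  }
  root_pt <- c(mean(ends$z) - 10, mean(ends$y), mean(ends$x))
  segs <- tibble::tibble(
    id = c(1L, seq_len(n) + 1L),
    parent_id = c(NA_integer_, rep(1L, n)),
    generation = c(0L, rep(1L, n)),
    points = c(list(cbind(c(root_pt[1] - 5, root_pt[1]), root_pt[2],
                          root_pt[3], 3)),
               lapply(seq_len(n), function(k)
                 cbind(c(root_pt[1], ends$z[k]),
                       c(root_pt[2], ends$y[k]),
                       c(root_pt[3], ends$x[k]), 2)))
  )
  airway_tree(segs, 1L)
}

test_that("region assignment is a nearest-terminal partition", {
  mask <- array(TRUE, c(20, 20, 20))
  # single terminal: everything assigned to it
  t1 <- mini_tree(tibble::tibble(z = 10, y = 10, x = 10))
  lab1 <- assign_regions(mask, t1)
  expect_true(all(lab1[mask] == 1L))
  # two terminals symmetric about a plane: half-space partition
  t2 <- mini_tree(tibble::tibble(z = c(10, 10), y = c(10, 10),
                                 x = c(4, 14)))
  lab2 <- assign_regions(mask, t2)
  g <- axis_grids_(dim(mask))
  expect_true(all(lab2[g$x < 9] == 2L))
  expect_true(all(lab2[g$x > 9] == 3L))
  # equidistant plane x == 9: tie broken towards the lowest id
  expect_true(all(lab2[g$x == 9] == 2L))
  expect_error(assign_regions(array(FALSE, c(4, 4, 4)), t1), "empty mask")
})

test_that("assignment agrees with the phantom's own region labels", {
  ph <- phantom_clean()
  track <- track_clean()
  asn <- assign_regions(track$expansions[[1]], ph$tree)
  truth <- ph$region_labels[cbind(round(asn$z) + 1, round(asn$y) + 1,
                                  round(asn$x) + 1)]
  inside <- truth > 0
  expect_gt(mean(asn$terminal_id[inside] == truth[inside]), 0.8)
})

test_that("regional volumes are linear in the expansion data", {
  ph <- phantom_clean()
  track <- track_clean()
  asn <- assign_regions(track$expansions[[1]], ph$tree)
  reg <- regional_volumes(track$expansions, asn, track$phase_times)
  expect_true(all(reg$volume[reg$phase == 0] == 0))
  # zero expansion -> identically zero series
  zeroed <- lapply(track$expansions, function(e) {
    e$expansion[] <- 0
    e$expansion_ls[] <- 0
    e
  })
  reg0 <- regional_volumes(zeroed, asn, track$phase_times)
  expect_equal(max(abs(reg0$volume)), 0)
  # uniform expansion -> volumes proportional to element counts
  ones <- lapply(track$expansions, function(e) {
    e$expansion[] <- 1e-3
    e$expansion_ls[] <- 1e-3
    e$valid[] <- TRUE
    e
  })
  reg1 <- regional_volumes(ones, asn, track$phase_times)
  peak <- reg1[reg1$phase == max(reg1$phase), ]
  counts <- table(asn$terminal_id)
  expect_equal(peak$volume / sum(peak$volume),
               as.numeric(counts[as.character(peak$id)]) / nrow(asn),
               tolerance = 1e-9)
  # doubling expansion doubles every volume
  doubled <- lapply(track$expansions, function(e) {
    e$expansion <- 2 * e$expansion
    e$expansion_ls <- 2 * e$expansion_ls
    e
  })
  reg2 <- regional_volumes(doubled, asn, track$phase_times)
  expect_equal(reg2$volume, 2 * reg$volume, tolerance = 1e-9)
})

test_that("flow summation conserves volume at every bifurcation", {
  ph <- phantom_defect()
  fl <- flow_sum(ph$tree, ph$truth$regional_volumes)
  segs <- ph$tree$segments
  parents <- unique(segs$parent_id[!is.na(segs$parent_id)])
  worst <- 0
  for (p in parents) {
    kids <- segs$id[!is.na(segs$parent_id) & segs$parent_id == p]
    pv <- fl$volume[fl$id == p]
    kv <- fl$volume[fl$id == kids[1]] + fl$volume[fl$id == kids[2]]
    worst <- max(worst, max(abs(pv - kv)) / max(max(abs(pv)), 1e-12))
  }
  expect_lt(worst, 1e-9)
  # trachea equals the sum over all terminals (telescoping)
  term <- terminal_ids(ph$tree)
  tra <- fl$volume[fl$id == ph$tree$root_id]
  tsum <- rowSums(sapply(term, function(id) fl$volume[fl$id == id]))
  expect_equal(tra, tsum, tolerance = 1e-12)
  # airflow is the finite difference of volume over the phase step
  s1 <- fl[fl$id == ph$tree$root_id, ]
  expect_equal(s1$flow[-1], diff(s1$volume) / diff(s1$time))
  # a terminal without a series is an error
  broken <- ph$truth$regional_volumes
  broken <- broken[broken$id != max(term), ]
  expect_error(flow_sum(ph$tree, broken), "no volume series")
})

test_that("the expiratory time constant recovers exponential decay", {
  prot <- ventilation_protocol()
  tt <- seq(0, 500, length.out = 16)[1:15]
  VT <- 10
  series <- function(tau) {
    tibble::tibble(
      id = 1L, phase = 0:14, time = tt,
      volume = ifelse(tt <= 250, VT * (1 - cos(pi * tt / 250)) / 2,
                      VT * exp(-(tt - 250) / tau)))
  }
  t1 <- mini_tree(tibble::tibble(z = 10, y = 10, x = 10))
  taus <- expiratory_time_constant(flow_sum(t1, series(100)), prot)
  expect_true(taus$valid)
  expect_lt(abs(taus$tau - 100) / 100, 0.05)
  # the threshold is 1 - 1/e (63% printed to two digits)
  expect_equal(round((1 - exp(-1)) * 100), 63)
  expect_equal(formals(expiratory_time_constant)$threshold,
               quote(1 - exp(-1)))
  # non-decaying series: invalid flag, no exception
  flat <- series(100)
  flat$volume[tt > 250] <- VT
  tf <- expiratory_time_constant(flow_sum(t1, flat), prot)
  expect_false(tf$valid)
  # scaling the series leaves tau unchanged
  big <- series(100)
  big$volume <- big$volume * 2
  tb <- expiratory_time_constant(flow_sum(t1, big), prot)
  expect_equal(tb$tau, taus$tau, tolerance = 1e-12)
  # exponential-fit route agrees on exact exponentials
  te <- expiratory_time_constant(flow_sum(t1, series(100)), prot,
                                 method = "expfit")
  expect_lt(abs(te$tau - 100) / 100, 0.02)
})

test_that("regional time constants separate defect from healthy regions", {
  ph <- phantom_defect()
  fl <- flow_sum(ph$tree, ph$truth$regional_volumes)
  taus <- expiratory_time_constant(fl, ph$spec$ventilation)
  term <- terminal_ids(ph$tree)
  tt <- taus[taus$id %in% term, ]
  truth <- ph$motion$terminal_tau
  m <- merge(tt, truth, by = "id")
  expect_true(all(m$valid))
  # both groups exist, and classification at the midpoint is error-free
  expect_setequal(unique(m$tau.y), c(80, 160))
  cls <- ifelse(m$tau.x > 120, 160, 80)
  expect_equal(sum(cls != m$tau.y), 0)
  # defect branches are strictly slower than healthy ones
  expect_gt(min(m$tau.x[m$tau.y == 160]), max(m$tau.x[m$tau.y == 80]))
})

test_that("the aeration map is anchored at FRC and grows during
           inspiration", {
  ph <- phantom_defect()
  fl <- flow_sum(ph$tree, ph$truth$regional_volumes)
  am <- aeration_map(fl, ph$tree)
  expect_equal(max(abs(am$volume[am$phase == 0])), 0)
  # during inspiration cumulative volume is non-decreasing everywhere
  insp <- am[am$time <= ph$spec$ventilation$t_insp, ]
  by_pt <- split(insp$volume[order(insp$id, insp$point, insp$time)],
                 paste(insp$id, insp$point)[order(insp$id, insp$point,
                                                  insp$time)])
  expect_true(all(vapply(by_pt, function(v) all(diff(v) >= -1e-9), TRUE)))
  # the trachea carries the whole-lung volume change
  tra <- am[am$id == ph$tree$root_id & am$point == 0, ]
  tra <- tra[order(tra$phase), ]
  expect_equal(tra$volume, ph$truth$total$volume, tolerance = 1e-9)
})
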