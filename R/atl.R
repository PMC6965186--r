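#' Assign lung elements to terminal airways
#'
#' Partitions lung tissue among the terminal airway segments: every element
#' (XV grid node, or voxel of a mask) is assigned to the nearest terminal
#' endpoint by Euclidean distance, ties broken towards the lowest segment
#' id.
#'
#' @param x either a tibble with voxel coordinates `z, y, x` (e.g. an
#'   `xv_field` or `xv_expansion`) or a logical 3D array mask
#' @param tree an [airway_tree()] with at least one terminal
#' @return for a tibble input, the tibble with a `terminal_id` column; for
#'   a mask, an integer label array (0 outside the mask)
#' @export
assign_regions <- function(x, tree) {
  ends <- terminal_endpoints(tree)
  if (!nrow(ends)) abort("tree has no terminal segments")
  if (is.array(x)) {
    if (!any(x)) abort("empty mask")
    d <- dim(x)
    g <- axis_grids(d)
    idx <- which(x)
    lab <- nearest_terminal(g$z[idx], g$y[idx], g$x[idx], ends)
    out <- array(0L, d)
    out[idx] <- lab
    return(out)
  }
  if (!all(c("z", "y", "x") %in% names(x)))
    abort("`x` must be a mask array or a tibble with z, y, x columns")
  if (!nrow(x)) abort("empty element table")
  x[["terminal_id"]] <- nearest_terminal(x[["z"]], x[["y"]], x[["x"]], ends)
  x
}

nearest_terminal <- function(z, y, x, ends) {
  best <- rep(Inf, length(z))
  lab <- integer(length(z))
  for (k in order(ends$id)) {
    d2 <- (z - ends$z[k])^2 + (y - ends$y[k])^2 + (x - ends$x[k])^2
    take <- d2 < best
    best[take] <- d2[take]
    lab[take] <- ends$id[k]
  }
  lab
}

#' Mask-weighted element volumes for XV grid nodes
#'
#' Volume represented by each interrogation node: the number of lung-mask
#' voxels closer to that node than to any other node (a rectangular-cell
#' partition of the mask), times the voxel volume.  Summed over nodes this
#' equals the mask volume exactly, making regional volume integrals
#' consistent with the voxel-level ground truth.
#'
#' @param grid a tibble of nodes (an `xv_field`, `xv_expansion` or
#'   [xv_grid()] output) with attributes `nnodes`, `spacing`, `origin`
#' @param lung_mask logical 3D array
#' @param voxel_size voxel edge length
#' @return numeric vector of element volumes, one per grid row
#' @export
node_cell_volumes <- function(grid, lung_mask, voxel_size = 1) {
  nn <- attr(grid, "nnodes")
  spacing <- attr(grid, "spacing")
  origin <- if (!is.null(attr(grid, "origin"))) attr(grid, "origin")
            else (attr(grid, "window") - 1) / 2
  d <- dim(lung_mask)
  g <- axis_grids(d)
  idx <- which(lung_mask)
  ni <- pmin(nn[1] - 1, pmax(0, round((g$z[idx] - origin) / spacing)))
  nj <- pmin(nn[2] - 1, pmax(0, round((g$y[idx] - origin) / spacing)))
  nk <- pmin(nn[3] - 1, pmax(0, round((g$x[idx] - origin) / spacing)))
  key <- ni + nn[1] * (nj + nn[2] * nk)
  counts <- tabulate(key + 1L, prod(nn))
  rows <- grid$i + nn[1] * (grid$j + nn[2] * grid$k) + 1L
  counts[rows] * voxel_size^3
}

#' Regional air-volume series at the terminal airways
#'
#' Integrates the measured expansion over each terminal's assigned lung
#' region, per breath interval, and accumulates over phases: the air volume
#' (relative to end-expiration) supplied through each terminal airway.
#'
#' @param expansions list of `xv_expansion` fields, one per successive phase
#'   interval (e.g. `track$expansions` from [track_breath()]), all on the
#'   same grid
#' @param assignment node assignment from [assign_regions()] run on the
#'   same grid (tibble with `terminal_id`), or — for the voxel-level method,
#'   when `lung_mask` is given — an integer region-label array from
#'   `assign_regions(lung_mask, tree)`
#' @param phase_times phase times (ms), length `length(expansions) + 1`
#' @param voxel_size voxel edge length
#' @param element_volumes per-node element volumes for the node-cell
#'   method; default is the uniform grid-cell volume
#'   `spacing^3 * voxel_size^3`, or use [node_cell_volumes()] for
#'   mask-weighted cells
#' @param lung_mask optional logical array; when given, the expansion field
#'   is re-projected to the grid nodes (local linear fit over the
#'   measurement positions) and trilinearly interpolated to every lung
#'   voxel, and regional volumes are voxel-level integrals — the more
#'   accurate quadrature when windows straddle the lung boundary
#' @return tibble with `id` (terminal segment), `phase`, `time`, `volume`
#'   (voxel_size^3 units, 0 at phase 0)
#' @export
regional_volumes <- function(expansions, assignment, phase_times,
                             voxel_size = 1, element_volumes = NULL,
                             lung_mask = NULL) {
  if (inherits(expansions, "xv_expansion")) expansions <- list(expansions)
  n_int <- length(expansions)
  if (length(phase_times) != n_int + 1)
    abort("`phase_times` must have one more entry than intervals")
  nnode <- nrow(expansions[[1]])
  if (!is.null(lung_mask)) {
    if (!is.array(assignment))
      abort("voxel-level integration needs a region-label array assignment")
    return(regional_volumes_voxel(expansions, assignment, phase_times,
                                  voxel_size, lung_mask, n_int))
  }
  if (nrow(assignment) != nnode)
    abort("assignment and expansion grids do not match")
  if (!all(c("i", "j", "k") %in% names(assignment)) ||
      !identical(assignment$i, expansions[[1]]$i) ||
      !identical(assignment$j, expansions[[1]]$j) ||
      !identical(assignment$k, expansions[[1]]$k))
    abort("assignment and expansion grids do not match")
  if (is.null(element_volumes)) {
    spacing <- attr(expansions[[1]], "spacing")
    element_volumes <- rep((spacing * voxel_size)^3, nnode)
  }
  ids <- sort(unique(assignment$terminal_id))
  fac <- factor(assignment$terminal_id, levels = ids)
  inc <- matrix(0, length(ids), n_int)
  for (t in seq_len(n_int)) {
    e <- expansions[[t]]
    # boundary nodes without a valid stencil inherit the nearest valid value
    v <- fill_from_valid(e)
    inc[, t] <- tapply(v * element_volumes, fac, sum, default = 0)
  }
  cum <- cbind(0, t(apply(inc, 1, cumsum)))
  tibble(
    id = rep(ids, times = n_int + 1),
    phase = rep(0:n_int, each = length(ids)),
    time = rep(phase_times, each = length(ids)),
    volume = as.numeric(cum)
  )
}

# voxel-level regional integration: re-project nodal expansion estimates
# from their measurement positions onto the regular node grid, interpolate
# trilinearly to every masked voxel, and sum per region label
regional_volumes_voxel <- function(expansions, labels, phase_times,
                                   voxel_size, lung_mask, n_int) {
  e1 <- expansions[[1]]
  nn <- attr(e1, "nnodes")
  spacing <- attr(e1, "spacing")
  origin <- (attr(e1, "window") - 1) / 2
  d <- dim(lung_mask)
  g <- axis_grids(d)
  vidx <- which(lung_mask)
  lab <- labels[vidx]
  if (any(lab == 0))
    abort("region labels must cover the whole lung mask")
  fi <- pmin(pmax((g$z[vidx] - origin) / spacing, 0), nn[1] - 1)
  fj <- pmin(pmax((g$y[vidx] - origin) / spacing, 0), nn[2] - 1)
  fk <- pmin(pmax((g$x[vidx] - origin) / spacing, 0), nn[3] - 1)
  i0 <- pmin(floor(fi), nn[1] - 2); fz <- fi - i0
  j0 <- pmin(floor(fj), nn[2] - 2); fy <- fj - j0
  k0 <- pmin(floor(fk), nn[3] - 2); fx <- fk - k0
  ids <- sort(unique(lab))
  fac <- factor(lab, levels = ids)
  inc <- matrix(0, length(ids), n_int)
  interp_to_voxels <- function(arr) {
    acc <- numeric(length(vidx))
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      wgt <- (di * fz + (1 - di) * (1 - fz)) *
        (dj * fy + (1 - dj) * (1 - fy)) *
        (dk * fx + (1 - dk) * (1 - fx))
      acc <- acc + wgt * arr[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
    }
    acc
  }
  # central-difference divergence of a voxel-level vector field (one-sided
  # at the volume faces)
  diverge <- function(uz, uy, ux) {
    dd <- dim(uz)
    dax <- function(a, ax) {
      n <- dd[ax]
      ip <- pmin(seq_len(n) + 1L, n)
      im <- pmax(seq_len(n) - 1L, 1L)
      den <- ip - im
      if (ax == 1) (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) /
          array(den, dd)
      else if (ax == 2) (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
          aperm(array(den, dd[c(2, 1, 3)]), c(2, 1, 3))
      else (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
          aperm(array(den, dd[c(3, 1, 2)]), c(2, 3, 1))
    }
    dax(uz, 1) + dax(uy, 2) + dax(ux, 3)
  }
  for (t in seq_len(n_int)) {
    e <- expansions[[t]]
    field <- attr(e, "field")
    if (!is.null(field)) {
      # interpolate the (nearly linear) displacement components to every
      # voxel and integrate their discrete divergence over each region:
      # better conditioned than extrapolating the divergence itself into
      # the boundary shell
      uz <- array(project_vector_to_nodes(field, field$u, nn), nn)
      uy <- array(project_vector_to_nodes(field, field$v, nn), nn)
      ux <- array(project_vector_to_nodes(field, field$w, nn), nn)
      # whole-grid interpolation so the divergence stencil is defined at
      # the mask border as well
      vz <- interp_to_voxels_all(uz, d, nn, origin, spacing)
      vy <- interp_to_voxels_all(uy, d, nn, origin, spacing)
      vx <- interp_to_voxels_all(ux, d, nn, origin, spacing)
      dvv <- diverge(vz, vy, vx)
      acc <- dvv[vidx]
    } else {
      vals <- project_expansion_to_nodes(e, nn)
      arr <- array(vals, nn)
      acc <- interp_to_voxels(arr)
    }
    inc[, t] <- tapply(acc, fac, sum, default = 0) * voxel_size^3
  }
  cum <- cbind(0, t(apply(inc, 1, cumsum)))
  tibble(
    id = rep(ids, times = n_int + 1),
    phase = rep(0:n_int, each = length(ids)),
    time = rep(phase_times, each = length(ids)),
    volume = as.numeric(cum)
  )
}


# interpolate node values to every voxel of the grid (clamped trilinear)
interp_to_voxels_all <- function(arr, d, nn, origin, spacing) {
  g <- axis_grids(d)
  fi <- pmin(pmax((g$z - origin) / spacing, 0), nn[1] - 1)
  fj <- pmin(pmax((g$y - origin) / spacing, 0), nn[2] - 1)
  fk <- pmin(pmax((g$x - origin) / spacing, 0), nn[3] - 1)
  i0 <- pmin(floor(fi), nn[1] - 2); fz <- fi - i0
  j0 <- pmin(floor(fj), nn[2] - 2); fy <- fj - j0
  k0 <- pmin(floor(fk), nn[3] - 2); fx <- fk - k0
  acc <- array(0, d)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wgt <- (di * fz + (1 - di) * (1 - fz)) *
      (dj * fy + (1 - dj) * (1 - fy)) *
      (dk * fx + (1 - dk) * (1 - fx))
    acc <- acc + wgt * arr[cbind(as.vector(i0 + di + 1),
                                 as.vector(j0 + dj + 1),
                                 as.vector(k0 + dk + 1))]
  }
  acc
}

# estimate one displacement component at each regular node position by a
# local linear fit over the usable vectors' measurement positions
project_vector_to_nodes <- function(field, vals, nn) {
  usable <- which(field$valid | field$replaced)
  out <- rep(NA_real_, nrow(field))
  pz <- field$mz; py <- field$my; px <- field$mx
  for (r in seq_len(nrow(field))) {
    nb <- usable[abs(field$i[usable] - field$i[r]) <= 1 &
                   abs(field$j[usable] - field$j[r]) <= 1 &
                   abs(field$k[usable] - field$k[r]) <= 1]
    if (length(nb) >= 6) {
      X <- cbind(1, pz[nb] - field$z[r], py[nb] - field$y[r],
                 px[nb] - field$x[r])
      beta <- tryCatch(qr.coef(qr(X), vals[nb]),
                       error = function(err) NULL)
      if (!is.null(beta) && is.finite(beta[1])) {
        out[r] <- beta[1]
        next
      }
    }
    if (length(nb)) out[r] <- vals[nb[which.min(
      (field$i[nb] - field$i[r])^2 + (field$j[nb] - field$j[r])^2 +
        (field$k[nb] - field$k[r])^2)]]
  }
  bad <- which(is.na(out))
  if (length(bad)) {
    for (r in bad) {
      d2 <- (field$i[usable] - field$i[r])^2 +
        (field$j[usable] - field$j[r])^2 +
        (field$k[usable] - field$k[r])^2
      out[r] <- vals[usable[which.min(d2)]]
    }
  }
  out
}

# estimate the expansion value at each regular node position by a local
# linear fit of the valid estimates over their true measurement positions;
# nodes without enough valid neighbours inherit the nearest valid value
project_expansion_to_nodes <- function(e, nn) {
  use_ls <- "expansion_ls" %in% names(e)
  base <- if (use_ls) e$expansion_ls else e$expansion
  bz <- if (use_ls) e$pz else e$ez
  by <- if (use_ls) e$py else e$ey
  bx <- if (use_ls) e$px else e$ex
  vals <- rep(NA_real_, nrow(e))
  good <- which(!is.na(base))
  if (!length(good)) return(rep(0, nrow(e)))
  for (r in seq_len(nrow(e))) {
    nb <- good[abs(e$i[good] - e$i[r]) <= 1 & abs(e$j[good] - e$j[r]) <= 1 &
                 abs(e$k[good] - e$k[r]) <= 1]
    if (length(nb) >= 5) {
      X <- cbind(1, bz[nb] - e$z[r], by[nb] - e$y[r], bx[nb] - e$x[r])
      beta <- tryCatch(qr.coef(qr(X), base[nb]),
                       error = function(err) NULL)
      if (!is.null(beta) && is.finite(beta[1])) {
        # the fit extrapolates; never leave the neighbourhood's value range
        vals[r] <- min(max(beta[1], min(base[nb])), max(base[nb]))
        next
      }
    }
    if (!is.na(base[r])) vals[r] <- base[r]
  }
  bad <- which(is.na(vals))
  for (r in bad) {
    d2 <- (e$i[good] - e$i[r])^2 + (e$j[good] - e$j[r])^2 +
      (e$k[good] - e$k[r])^2
    vals[r] <- base[good[which.min(d2)]]
  }
  vals
}

# replace invalid expansion values by the value of the nearest valid node
fill_from_valid <- function(e) {
  v <- e$expansion
  bad <- which(!e$valid)
  if (!length(bad)) return(v)
  good <- which(e$valid)
  if (!length(good)) {
    v[] <- 0
    return(v)
  }
  for (r in bad) {
    d2 <- (e$i[good] - e$i[r])^2 + (e$j[good] - e$j[r])^2 +
      (e$k[good] - e$k[r])^2
    v[r] <- v[good[which.min(d2)]]
  }
  v
}

#' Recursive airflow summation up the airway tree
#'
#' Builds the full per-branch air-volume and airflow series from the
#' terminal series by post-order traversal: a leaf's series is its own
#' regional series, an internal segment's series is the sum of its two
#' daughters', so flow through a parent equals the sum of the daughter
#' flows at every phase (airway compression neglected).
#'
#' @param tree an [airway_tree()]
#' @param terminal_series tibble with `id`, `phase`, `time`, `volume` for
#'   every terminal segment (see [regional_volumes()])
#' @return a `branch_flow_series` tibble: `id`, `parent_id`, `generation`,
#'   `phase`, `time`, `volume`, `flow` (volume per ms; `NA` at phase 0)
#' @export
flow_sum <- function(tree, terminal_series) {
  term <- sort(terminal_ids(tree))
  missing <- setdiff(term, unique(terminal_series$id))
  if (length(missing))
    abort(sprintf("no volume series for terminal segment(s): %s",
                  paste(missing, collapse = ", ")))
  times <- sort(unique(terminal_series$time))
  nph <- length(times)
  tmat <- matrix(0, nph, length(term), dimnames = list(NULL, term))
  for (id in term) {
    s <- terminal_series[terminal_series$id == id, ]
    s <- s[order(s$time), ]
    if (nrow(s) != nph) abort("terminal series must share the phase grid")
    tmat[, as.character(id)] <- s$volume
  }
  segs <- tree$segments
  vol <- matrix(NA_real_, nph, nrow(segs),
                dimnames = list(NULL, segs$id))
  series_of <- function(id) {
    col <- as.character(id)
    if (!anyNA(vol[, col])) return(vol[, col])
    kids <- segment_children(tree, id)
    v <- if (!length(kids)) tmat[, col]
         else series_of(kids[1]) + series_of(kids[2])
    vol[, col] <<- v
    v
  }
  for (id in segs$id) series_of(id)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
    v <- vol[, as.character(segs$id[i])]
    tibble(
      id = segs$id[i], parent_id = segs$parent_id[i],
      generation = segs$generation[i],
      phase = 0:(nph - 1), time = times, volume = v,
      flow = c(NA_real_, diff(v) / diff(times))
    )
  }))
  class(out) <- c("branch_flow_series", class(out))
  attr(out, "tree") <- tree
  out
}

#' @export
glance.branch_flow_series <- function(x, ...) {
  tr <- attr(x, "tree")
  root <- x[x$id == tr$root_id, ]
  tibble(
    n_segments = length(unique(x$id)),
    n_phases = length(unique(x$phase)),
    tidal_volume = max(root$volume),
    peak_time = root$time[which.max(root$volume)]
  )
}

#' @export
autoplot.branch_flow_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$volume,
                               group = .data$id,
                               colour = factor(.data$generation))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time in breath (ms)",
                  y = "air volume passed (relative to end-expiration)",
                  colour = "generation")
}

#' Expiratory time constant per airway branch
#'
#' The regional time constant tau: the time after the start of expiration
#' at which the branch's expired volume first reaches `1 - 1/e` (~63%) of
#' its tidal volume, located by linear interpolation between phase samples.
#' Branches with non-positive tidal volume or that never reach the
#' threshold are flagged invalid, not errors.  Expiration starts at the
#' ventilation protocol's `t_insp` (ventilator-triggered acquisition makes
#' protocol time authoritative); `start = "peak"` instead uses each
#' branch's measured volume peak.
#'
#' @param flow a `branch_flow_series` from [flow_sum()]
#' @param protocol a [ventilation_protocol()]
#' @param threshold expired fraction defining tau (default `1 - 1/e`)
#' @param method `"crossing"` (threshold with linear interpolation, the
#'   operational definition) or `"expfit"` (log-linear exponential fit over
#'   expiration)
#' @param start `"protocol"` or `"peak"`
#' @return a `tau_map` tibble: `id`, `generation`, `tidal_volume`, `tau`
#'   (ms), `valid`
#' @export
expiratory_time_constant <- function(flow, protocol,
                                     threshold = 1 - exp(-1),
                                     method = c("crossing", "expfit"),
                                     start = c("protocol", "peak")) {
  method <- match.arg(method)
  start <- match.arg(start)
  ids <- unique(flow$id)
  rows <- lapply(ids, function(id) {
    s <- flow[flow$id == id, ]
    s <- s[order(s$time), ]
    tidal <- max(s$volume)
    gen <- s$generation[1]
    t0 <- if (start == "protocol") protocol$t_insp
          else s$time[which.max(s$volume)]
    if (!is.finite(tidal) || tidal <= 0)
      return(tibble(id = id, generation = gen, tidal_volume = tidal,
                    tau = NA_real_, valid = FALSE))
    # volume at the start of expiration (linear interpolation)
    v0 <- approx(s$time, s$volume, xout = t0, rule = 2)$y
    exp_t <- s$time[s$time > t0]
    exp_v <- s$volume[s$time > t0]
    if (!length(exp_t))
      return(tibble(id = id, generation = gen, tidal_volume = tidal,
                    tau = NA_real_, valid = FALSE))
    if (method == "expfit") {
      ok <- exp_v > 0
      if (sum(ok) < 2)
        return(tibble(id = id, generation = gen, tidal_volume = tidal,
                      tau = NA_real_, valid = FALSE))
      fit <- stats::lm(log(exp_v[ok]) ~ exp_t[ok])
      slope <- stats::coef(fit)[2]
      tau <- if (slope < 0) -1 / slope else NA_real_
      return(tibble(id = id, generation = gen, tidal_volume = tidal,
                    tau = tau, valid = is.finite(tau)))
    }
    # expired volume is measured against the tidal peak, so the crossing
    # is where V(t) first falls below (1 - threshold) * tidal
    target_v <- (1 - threshold) * tidal
    vv <- c(v0, exp_v)
    tt <- c(t0, exp_t)
    below <- which(vv <= target_v)
    if (!length(below))
      return(tibble(id = id, generation = gen, tidal_volume = tidal,
                    tau = NA_real_, valid = FALSE))
    a <- below[1]
    tau <- if (a == 1) 0 else {
      frac <- (vv[a - 1] - target_v) / (vv[a - 1] - vv[a])
      tt[a - 1] + frac * (tt[a] - tt[a - 1]) - t0
    }
    tibble(id = id, generation = gen, tidal_volume = tidal, tau = tau,
           valid = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tau_map", class(out))
  attr(out, "tree") <- attr(flow, "tree")
  out
}

#' Cumulative aeration map along the airway tree
#'
#' For every centerline location, the measured air volume (relative to
#' end-expiration) that has passed that location up to each time point —
#' a location inherits its segment's cumulative volume series.
#'
#' @param flow a `branch_flow_series` from [flow_sum()]
#' @param tree the [airway_tree()] the series was computed on (defaults to
#'   the tree attached to `flow`)
#' @return tibble with `id`, `generation`, `point`, `z`, `y`, `x`, `phase`,
#'   `time`, `volume`
#' @export
aeration_map <- function(flow, tree = attr(flow, "tree")) {
  segs <- tree$segments
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
    p <- segs$points[[i]]
    tibble(id = segs$id[i], generation = segs$generation[i],
           point = seq_len(nrow(p)) - 1L,
           z = p[, 1], y = p[, 2], x = p[, 3])
  }))
  dplyr::inner_join(pts,
                    flow[, c("id", "phase", "time", "volume")],
                    by = "id", relationship = "many-to-many")
}

#' @export
autoplot.tau_map <- function(object, ...) {
  tr <- attr(object, "tree")
  if (is.null(tr)) abort("tau_map has no attached tree to draw")
  segs <- tr$segments
  df <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
    p <- segs$points[[i]]
    tibble(id = segs$id[i], z = p[, 1], x = p[, 3])
  }))
  df <- dplyr::left_join(df, object[, c("id", "tau")], by = "id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$id, colour = .data$tau)) +
    ggplot2::geom_path(linewidth = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "tau (ms)", x = "x (voxels)", y = "z (voxels)")
}
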