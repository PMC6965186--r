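#' Rooted airway-tree graph
#'
#' An airway tree is a rooted binary tree of airway segments.  Each segment
#' carries a polyline centerline in 0-based voxel coordinates (axis order
#' z, y, x) and a radius per centerline point.  Generation 0 is the trachea;
#' every bifurcation has exactly two children and child radii are strictly
#' smaller than their parent's.
#'
#' @param segments a tibble with columns `id` (integer), `parent_id`
#'   (integer, `NA` for the root), `generation` (integer) and `points`
#'   (list of numeric matrices with columns z, y, x, r)
#' @param root_id id of the trachea segment
#' @param validate check the tree invariants (default `TRUE`)
#' @return an object of class `airway_tree`
#' @export
airway_tree <- function(segments, root_id, validate = TRUE) {
  tr <- structure(list(segments = as_tibble(segments), root_id = root_id),
                  class = "airway_tree")
  if (validate) validate_airway_tree(tr)
  tr
}

#' @rdname airway_tree
#' @param tree an `airway_tree`
#' @param check_radii also enforce strict child < parent radius decay
#'   (guaranteed for generated trees; only approximate for trees measured
#'   from images)
#' @export
validate_airway_tree <- function(tree, check_radii = TRUE) {
  s <- tree$segments
  roots <- s$id[is.na(s$parent_id)]
  if (length(roots) != 1 || roots != tree$root_id)
    abort("tree must have exactly one root (the trachea)")
  if (any(s$generation[is.na(s$parent_id)] != 0))
    abort("the root must be generation 0")
  if (anyDuplicated(s$id)) abort("segment ids must be unique")
  kids <- table(factor(s$parent_id, levels = s$id))
  if (!all(kids %in% c(0L, 2L)))
    abort("every bifurcation must have exactly 2 children")
  # connectivity/acyclicity: walk every segment up to the root
  parent <- setNames(s$parent_id, s$id)
  for (id in s$id) {
    seen <- integer()
    cur <- id
    while (!is.na(parent[[as.character(cur)]])) {
      if (cur %in% seen) abort("tree contains a cycle")
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
      if (!cur %in% s$id) abort("dangling parent_id")
    }
    if (cur != tree$root_id) abort("tree is not connected to the root")
  }
  if (check_radii) {
    rad <- setNames(vapply(s$points, function(p) mean(p[, 4]), 0), s$id)
    for (i in seq_len(nrow(s))) {
      pid <- s$parent_id[i]
      if (!is.na(pid) && rad[[as.character(s$id[i])]] >=
            rad[[as.character(pid)]])
        abort(sprintf("segment %d radius must be < parent radius", s$id[i]))
    }
  }
  invisible(tree)
}

#' @export
print.airway_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<airway_tree> %d segments, %d terminals, generations 0..%d\n",
    g$n_segments, g$n_terminals, g$max_generation))
  invisible(x)
}

#' Terminal (leaf) segment ids of an airway tree
#' @param tree an [airway_tree()]
#' @return integer vector of segment ids with no children
#' @export
terminal_ids <- function(tree) {
  s <- tree$segments
  setdiff(s$id, s$parent_id[!is.na(s$parent_id)])
}

#' Terminal endpoints of an airway tree
#'
#' The distal centerline point of every terminal segment — the locations the
#' ATL analysis treats as the supply points of the lung tissue.
#'
#' @param tree an [airway_tree()]
#' @return tibble with columns `id`, `z`, `y`, `x`
#' @export
terminal_endpoints <- function(tree) {
  ids <- sort(terminal_ids(tree))
  s <- tree$segments
  pts <- lapply(ids, function(i) {
    p <- s$points[[match(i, s$id)]]
    p[nrow(p), 1:3]
  })
  m <- do.call(rbind, pts)
  tibble(id = ids, z = m[, 1], y = m[, 2], x = m[, 3])
}

segment_children <- function(tree, id) {
  s <- tree$segments
  s$id[!is.na(s$parent_id) & s$parent_id == id]
}

#' @export
tidy.airway_tree <- function(x, ...) {
  s <- x$segments
  term <- terminal_ids(x)
  tibble(
    id = s$id, parent_id = s$parent_id, generation = s$generation,
    length = vapply(s$points, function(p) {
      if (nrow(p) < 2) return(0)
      sum(sqrt(rowSums(diff(p[, 1:3, drop = FALSE])^2)))
    }, 0),
    mean_radius = vapply(s$points, function(p) mean(p[, 4]), 0),
    terminal = s$id %in% term
  )
}

#' @export
glance.airway_tree <- function(x, ...) {
  s <- x$segments
  tibble(
    n_segments = nrow(s),
    n_terminals = length(terminal_ids(x)),
    n_bifurcations = nrow(s) - length(terminal_ids(x)),
    max_generation = max(s$generation)
  )
}

#' @export
autoplot.airway_tree <- function(object, ...) {
  s <- object$segments
  df <- dplyr::bind_rows(lapply(seq_len(nrow(s)), function(i) {
    p <- s$points[[i]]
    tibble(id = s$id[i], generation = s$generation[i],
           z = p[, 1], x = p[, 3])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   group = .data$id,
                                   colour = factor(.data$generation))) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "generation", x = "x (voxels)", y = "z (voxels)")
}

#' @export
plot.airway_tree <- function(x, ...) print(autoplot(x, ...))

# Rodrigues rotation of vector v about unit axis k by angle a
rotate_about <- function(v, k, a) {
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic airway tree
#'
#' Builds a full binary airway tree by recursive branching inside the
#' phantom's lung envelope: segment lengths and radii decay geometrically
#' down the generations, branch angles carry seeded jitter, and the
#' branching plane rotates between generations, giving a space-filling
#' three-dimensional tree.  A tree of `g` generations has `2^(g+1) - 1`
#' segments and `2^g` terminals.
#'
#' @param spec a [phantom_spec()]
#' @return an [airway_tree()]
#' @examples
#' tr <- generate_airway_tree(phantom_spec(grid_shape = c(48, 48, 48),
#'                                         tree_generations = 3))
#' glance(tr)
#' @export
generate_airway_tree <- function(spec) {
  dim <- spec$grid_shape
  g <- spec$tree_generations
  ctr <- (dim - 1) / 2
  semi <- 0.42 * dim
  rng <- local({
    set.seed(derive_seed(spec$seed, 1L))
    # pre-draw all jitter so tree shape is independent of traversal order
    n_max <- 2^(g + 2)
    list(ang = runif(n_max, -8, 8) * pi / 180,
         azi = runif(n_max, -20, 20) * pi / 180)
  })
  len0 <- 0.45 * semi[1]
  rad0 <- max(2.5, 0.05 * min(dim))
  len_ratio <- 0.78
  rad_ratio <- 0.75
  half_angle <- 33 * pi / 180

  segs <- list()
  next_id <- 1L
  check_bounds <- function(p, id) {
    if (any(p[, 1:3] < 1) || any(p[, 1] > dim[1] - 2) ||
        any(p[, 2] > dim[2] - 2) || any(p[, 3] > dim[3] - 2))
      abort(sprintf("airway tree exceeds grid bounds at segment %d", id))
  }
  make_points <- function(start, dir, len, rad) {
    n <- max(2L, ceiling(len))
    t <- seq(0, len, length.out = n)
    cbind(start[1] + t * dir[1], start[2] + t * dir[2],
          start[3] + t * dir[3], rad)
  }
  # normal used to define the branching plane, rotated per generation
  grow <- function(start, dir, normal, gen, parent_id, slot) {
    id <- next_id; next_id <<- next_id + 1L
    len <- len0 * len_ratio^gen
    rad <- rad0 * rad_ratio^gen
    pts <- make_points(start, dir, len, rad)
    check_bounds(pts, id)
    segs[[id]] <<- list(id = id, parent_id = parent_id, generation = gen,
                        points = pts)
    if (gen < g) {
      endp <- pts[nrow(pts), 1:3]
      a <- half_angle + rng$ang[2 * id]
      b <- half_angle + rng$ang[2 * id + 1]
      # rotate the branching plane around the parent direction
      roll <- pi / 2 + rng$azi[id]
      normal2 <- rotate_about(normal, dir, roll)
      normal2 <- normal2 / sqrt(sum(normal2^2))
      d1 <- rotate_about(dir, normal2, a)
      d2 <- rotate_about(dir, normal2, -b)
      grow(endp, d1 / sqrt(sum(d1^2)), normal2, gen + 1L, id, 1L)
      grow(endp, d2 / sqrt(sum(d2^2)), normal2, gen + 1L, id, 2L)
    }
    invisible(NULL)
  }
  start <- c(ctr[1] - 0.95 * semi[1], ctr[2], ctr[3])
  grow(start, c(1, 0, 0), c(0, 1, 0), 0L, NA_integer_, 1L)

  segments <- tibble(
    id = vapply(segs, `[[`, 0L, "id"),
    parent_id = vapply(segs, `[[`, 0L, "parent_id"),
    generation = vapply(segs, `[[`, 0L, "generation"),
    points = lapply(segs, `[[`, "points")
  )
  airway_tree(segments, root_id = 1L)
}
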