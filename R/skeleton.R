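# Skeletonization of a binary airway mask into a rooted segment tree.

# spanning tree of skeleton voxels by BFS from the root voxel (26-conn)
skeleton_voxel_tree <- function(skel, root_voxel) {
  d <- dim(skel)
  idx <- which(skel)
  if (!length(idx)) abort("empty skeleton")
  vid <- array(0L, d)
  vid[idx] <- seq_along(idx)
  nvox <- length(idx)
  zyx <- cbind((idx - 1) %% d[1],
               ((idx - 1) %/% d[1]) %% d[2],
               (idx - 1) %/% (d[1] * d[2]))
  # root = skeleton voxel nearest the requested root
  d2 <- (zyx[, 1] - root_voxel[1])^2 + (zyx[, 2] - root_voxel[2])^2 +
    (zyx[, 3] - root_voxel[3])^2
  root <- which.min(d2)
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  parent <- rep(NA_integer_, nvox)
  visited <- logical(nvox)
  visited[root] <- TRUE
  queue <- root
  children <- vector("list", nvox)
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    p <- zyx[cur, ]
    for (k in seq_len(nrow(off))) {
      q <- p + off[k, ]
      if (any(q < 0) || q[1] >= d[1] || q[2] >= d[2] || q[3] >= d[3]) next
      j <- vid[q[1] + 1, q[2] + 1, q[3] + 1]
      if (j == 0L || visited[j]) next
      visited[j] <- TRUE
      parent[j] <- cur
      children[[cur]] <- c(children[[cur]], j)
      queue <- c(queue, j)
    }
  }
  if (!all(visited))
    warn("skeleton has disconnected voxels; using the root's component")
  list(zyx = zyx, parent = parent, children = children, root = root)
}

# walk the voxel tree into polyline segments split at bifurcations
extract_segments <- function(vt, radius_at) {
  segs <- list()
  next_id <- 1L
  # stack entries: (start voxel, parent segment id, lead voxel from junction)
  walk <- function(start, parent_seg, prefix) {
    path <- prefix
    cur <- start
    repeat {
      path <- c(path, cur)
      kids <- vt$children[[cur]]
      if (length(kids) == 1) {
        cur <- kids
      } else break
    }
    id <- next_id; next_id <<- next_id + 1L
    segs[[id]] <<- list(id = id, parent_id = parent_seg, voxels = path)
    kids <- vt$children[[path[length(path)]]]
    for (k in kids) walk(k, id, path[length(path)])
    invisible(NULL)
  }
  walk(vt$root, NA_integer_, integer())
  segs
}

# drop spur segments shorter than prune_factor * local radius, then merge
# chains left with a single child
prune_and_merge <- function(segs, vt, radius_at, prune_factor) {
  repeat {
    ids <- vapply(segs, `[[`, 0L, "id")
    parents <- vapply(segs, `[[`, 0L, "parent_id")
    is_leaf <- !(ids %in% parents[!is.na(parents)])
    drop <- logical(length(segs))
    for (i in seq_along(segs)) {
      if (!is_leaf[i] || is.na(parents[i])) next
      vox <- segs[[i]]$voxels
      len <- seg_voxel_length(vt$zyx[vox, , drop = FALSE])
      base_r <- radius_at[vox[1]]
      if (len < prune_factor * base_r) drop[i] <- TRUE
    }
    if (!any(drop)) break
    # never drop all children of a node in the same pass: keep the longest
    for (p in unique(parents[drop & !is.na(parents)])) {
      kids <- which(!is.na(parents) & parents == p)
      if (all(drop[kids]) && length(kids) > 0) {
        lens <- vapply(kids, function(i)
          seg_voxel_length(vt$zyx[segs[[i]]$voxels, , drop = FALSE]), 0)
        drop[kids[which.max(lens)]] <- FALSE
      }
    }
    if (!any(drop)) break
    segs <- segs[!drop]
    # merge parents left with exactly one child
    repeat {
      ids <- vapply(segs, `[[`, 0L, "id")
      parents <- vapply(segs, `[[`, 0L, "parent_id")
      nkids <- table(factor(parents, levels = ids))
      single <- ids[nkids == 1]
      if (!length(single)) break
      p <- single[1]
      ci <- which(!is.na(parents) & parents == p)
      pi <- which(ids == p)
      segs[[pi]]$voxels <- c(segs[[pi]]$voxels, segs[[ci]]$voxels[-1])
      for (j in seq_along(segs))
        if (!is.na(segs[[j]]$parent_id) && segs[[j]]$parent_id == ids[ci])
          segs[[j]]$parent_id <- p
      segs <- segs[-ci]
    }
  }
  segs
}

seg_voxel_length <- function(zyx) {
  if (nrow(zyx) < 2) return(0)
  sum(sqrt(rowSums(diff(zyx)^2)))
}

# ensure every junction is binary by cascading extra children through
# zero-length intermediate segments
binarise_junctions <- function(segs) {
  repeat {
    ids <- vapply(segs, `[[`, 0L, "id")
    parents <- vapply(segs, `[[`, 0L, "parent_id")
    nkids <- table(factor(parents, levels = ids))
    bad <- ids[nkids > 2]
    if (!length(bad)) return(segs)
    p <- bad[1]
    kids <- which(!is.na(parents) & parents == p)
    pi <- which(ids == p)
    newid <- max(ids) + 1L
    tailvox <- tail(segs[[pi]]$voxels, 2)
    segs[[length(segs) + 1]] <- list(id = newid, parent_id = p,
                                     voxels = tailvox)
    for (ci in kids[-1]) segs[[ci]]$parent_id <- newid
  }
}

#' Skeletonize an airway mask into a rooted tree
#'
#' Thins the mask to a unit-width curve skeleton (topology-preserving
#' sequential thinning ordered by the distance transform), converts the
#' skeleton to a centerline graph rooted at the trachea, prunes spurs
#' shorter than `prune_factor` times the local airway radius, and assigns
#' generations by bifurcation count from the root.  The radius at each
#' centerline point is the distance-transform value of the mask.
#'
#' @param mask logical 3D array, one connected airway component
#' @param root_voxel trachea voxel `c(z, y, x)` (0-based); the skeleton
#'   voxel nearest this position becomes the root
#' @param prune_factor spur-prune length in units of the local radius
#' @return an [airway_tree()]
#' @export
skeletonize_to_tree <- function(mask, root_voxel, prune_factor = 2) {
  if (!is.array(mask) || length(dim(mask)) != 3) abort("`mask` must be 3D")
  mask <- mask != 0
  rv <- as.integer(root_voxel)
  if (!mask[rv[1] + 1, rv[2] + 1, rv[3] + 1])
    abort("root_voxel is not inside the mask")
  comp <- cpp_flood_fill26(mask, dim(mask), rv)
  if (any(mask & !comp))
    abort("mask is disconnected: multiple 26-connected components")
  radius <- cpp_edt(mask, dim(mask))
  skel <- cpp_skeletonize(mask, dim(mask))
  vt <- skeleton_voxel_tree(skel, rv)
  lin <- vt$zyx[, 1] + dim(mask)[1] * (vt$zyx[, 2] + dim(mask)[2] * vt$zyx[, 3]) + 1
  radius_at <- radius[lin]
  segs <- extract_segments(vt, radius_at)
  segs <- prune_and_merge(segs, vt, radius_at, prune_factor)
  segs <- binarise_junctions(segs)
  # relabel ids consecutively, root first, and assign generations
  ids <- vapply(segs, `[[`, 0L, "id")
  parents <- vapply(segs, `[[`, 0L, "parent_id")
  root_i <- which(is.na(parents))
  gen <- rep(NA_integer_, length(segs))
  gen[root_i] <- 0L
  while (anyNA(gen)) {
    for (i in seq_along(segs)) {
      if (!is.na(gen[i])) next
      pi <- which(ids == parents[i])
      if (!is.na(gen[pi])) gen[i] <- gen[pi] + 1L
    }
  }
  ord <- order(gen, ids)
  newid <- seq_along(segs)
  remap <- setNames(newid, ids[ord])
  segments <- tibble(
    id = newid,
    parent_id = vapply(seq_along(ord), function(k) {
      p <- parents[ord[k]]
      if (is.na(p)) NA_integer_ else as.integer(remap[[as.character(p)]])
    }, 0L),
    generation = gen[ord],
    points = lapply(ord, function(k) {
      vox <- segs[[k]]$voxels
      cbind(vt$zyx[vox, , drop = FALSE], radius_at[vox])
    })
  )
  tr <- airway_tree(segments, root_id = 1L, validate = FALSE)
  validate_airway_tree(tr, check_radii = FALSE)
  tr
}

#' Segment the airway tree from a gated 4D CT series
#'
#' Runs the segmentation chain — multiscale tubularity, flood fill,
#' skeletonization — on the first (end-expiration) phase only, where distal
#' gas volume is minimal and airway contrast maximal.
#'
#' @param volume4d a [volume4d()] (or a single 3D array)
#' @param params a [vesselness_params()]
#' @param seed_voxel trachea seed `c(z, y, x)` (0-based)
#' @param threshold flood-fill threshold; `NULL` for Otsu
#' @param prune_factor see [skeletonize_to_tree()]
#' @param min_voxels smallest credible airway mask; a smaller flood-fill
#'   result raises an error (degenerate input)
#' @return an [airway_tree()]
#' @export
segment_airways <- function(volume4d, params = vesselness_params(),
                            seed_voxel, threshold = NULL, prune_factor = 2,
                            min_voxels = 50) {
  vol <- if (inherits(volume4d, "volume4d")) volume4d$phases[[1]] else volume4d
  assert_volume3(vol)
  tub <- multiscale_tubularity(vol, params)
  mask <- flood_fill_segment(tub, seed_voxel, threshold)
  if (sum(mask) < min_voxels)
    abort(sprintf("segmented component too small (%d voxels < %d)",
                  sum(mask), min_voxels))
  skeletonize_to_tree(mask, seed_voxel, prune_factor)
}
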