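# Volume, tree and field I/O: TIFF stacks, NIfTI, VTK polylines, CSV.

#' Read or write a 3D volume
#'
#' Supported formats, chosen by file extension: multi-page TIFF stacks
#' (`.tif`/`.tiff`, 32-bit samples, one page per z slice; round-trips to
#' within 32-bit quantisation) and NIfTI (`.nii`, float64 — the lossless
#' round-trip format, with the voxel size carried in the header).
#'
#' @param path file path
#' @param volume numeric 3D array (axis order z, y, x)
#' @param voxel_size voxel edge length, stored in NIfTI metadata
#' @return `read_volume`: list with `volume` and `voxel_size` (`NA` when the
#'   format carries none); `write_volume`: the path, invisibly
#' @export
write_volume <- function(volume, path, voxel_size = 1) {
  assert_volume3(volume)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    slices <- lapply(seq_len(dim(volume)[1]), function(z)
      volume[z, , ])
    tiff::writeTIFF(slices, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(
      aperm(volume, c(3, 2, 1)),
      reference = list(pixdim = c(-1, rep(voxel_size, 3), rep(0, 4))),
      datatype = "double")
    RNifti::writeNifti(img, path)
  } else {
    abort(sprintf("unsupported volume format '.%s' (use .tif/.tiff or .nii)",
                  ext))
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    slices <- tiff::readTIFF(path, all = TRUE)
    vol <- array(0, c(length(slices), dim(slices[[1]])[1],
                      dim(slices[[1]])[2]))
    for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
    list(volume = vol, voxel_size = NA_real_)
  } else if (ext == "nii") {
    img <- RNifti::readNifti(path)
    vol <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
    list(volume = vol, voxel_size = RNifti::pixdim(img)[1])
  } else {
    abort(sprintf("unsupported volume format '.%s' (use .tif/.tiff or .nii)",
                  ext))
  }
}

#' Write or read a 4D breath series as one volume file per phase
#'
#' Files are named `<prefix>_<phase>` with a zero-padded phase index, plus a
#' `<prefix>_times.csv` sidecar holding phase times and the voxel size.
#'
#' @param v4d a [volume4d()]
#' @param dir output directory (created if needed)
#' @param format `"nii"` or `"tiff"`
#' @param prefix file-name prefix
#' @return `write_volume4d`: the directory, invisibly; `read_volume4d`: a
#'   [volume4d()]
#' @export
write_volume4d <- function(v4d, dir, format = c("nii", "tiff"),
                           prefix = "phase") {
  format <- match.arg(format)
  ext <- if (format == "nii") "nii" else "tif"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_phases(v4d)
  for (i in seq_len(n)) {
    f <- file.path(dir, sprintf("%s_%02d.%s", prefix, i - 1, ext))
    write_volume(v4d$phases[[i]], f, v4d$voxel_size)
  }
  readr::write_csv(
    tibble(phase = seq_len(n) - 1, time_ms = v4d$phase_times,
           voxel_size = v4d$voxel_size),
    file.path(dir, paste0(prefix, "_times.csv")))
  invisible(dir)
}

#' @rdname write_volume4d
#' @export
read_volume4d <- function(dir, prefix = "phase") {
  meta_f <- file.path(dir, paste0(prefix, "_times.csv"))
  if (!file.exists(meta_f)) abort(sprintf("file not found: %s", meta_f))
  meta <- readr::read_csv(meta_f, show_col_types = FALSE)
  files <- list.files(dir, sprintf("^%s_\\d+\\.(tif|tiff|nii)$", prefix),
                      full.names = TRUE)
  files <- sort(files)
  if (length(files) != nrow(meta)) abort("phase files do not match sidecar")
  phases <- lapply(files, function(f) read_volume(f)$volume)
  volume4d(phases, voxel_size = meta$voxel_size[1],
           phase_times = meta$time_ms)
}

#' Export an airway tree as a VTK polyline file
#'
#' Legacy ASCII VTK polydata: one polyline per segment with per-point
#' radius and generation scalars, plus an optional extra per-segment scalar
#' (e.g. cumulative aeration volume or expiratory time constant) broadcast
#' to the segment's points.
#'
#' @param tree an [airway_tree()]
#' @param path output `.vtk` path
#' @param values optional tibble with columns `id` and one value column to
#'   attach per segment
#' @return the path, invisibly
#' @export
write_tree_vtk <- function(tree, path, values = NULL) {
  segs <- tree$segments
  npts <- vapply(segs$points, nrow, 0L)
  total <- sum(npts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "airway tree", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", total)), con)
  for (p in segs$points)
    writeLines(sprintf("%.4f %.4f %.4f", p[, 3], p[, 2], p[, 1]), con)
  writeLines(sprintf("LINES %d %d", nrow(segs), nrow(segs) + total), con)
  offset <- 0L
  for (i in seq_len(nrow(segs))) {
    writeLines(paste(c(npts[i], offset:(offset + npts[i] - 1L)),
                     collapse = " "), con)
    offset <- offset + npts[i]
  }
  writeLines(sprintf("POINT_DATA %d", total), con)
  writeLines(c("SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  for (p in segs$points) writeLines(sprintf("%.4f", p[, 4]), con)
  writeLines(c("SCALARS generation float 1", "LOOKUP_TABLE default"), con)
  for (i in seq_len(nrow(segs)))
    writeLines(sprintf("%d", rep(segs$generation[i], npts[i])), con)
  if (!is.null(values)) {
    vname <- setdiff(names(values), "id")[1]
    v <- values[[vname]][match(segs$id, values$id)]
    v[!is.finite(v)] <- -1
    writeLines(c(sprintf("SCALARS %s float 1", vname),
                 "LOOKUP_TABLE default"), con)
    for (i in seq_len(nrow(segs)))
      writeLines(sprintf("%.6g", rep(v[i], npts[i])), con)
  }
  invisible(path)
}

#' Export a displacement field as CSV
#'
#' One row per interrogation node: node coordinates (z, y, x, voxels),
#' displacement components (u, v, w along z, y, x), quality, validity and
#' replacement flags.
#'
#' @param field an `xv_field` (or `xv_expansion`)
#' @param path output `.csv` path
#' @return the path, invisibly
#' @export
write_field_csv <- function(field, path) {
  readr::write_csv(as_tibble(field), path)
  invisible(path)
}
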