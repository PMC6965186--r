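#' Respiratory-gated 4D volume
#'
#' An ordered sequence of 3D intensity volumes, one per respiratory time
#' bin, with voxel-size metadata.  The first phase is end-expiration
#' (`phase_times[1] == 0`).
#'
#' @param phases list of numeric 3D arrays, all the same shape
#' @param voxel_size voxel edge length
#' @param phase_times strictly increasing times (ms) within the breath,
#'   starting at 0
#' @return an object of class `volume4d`
#' @export
volume4d <- function(phases, voxel_size = 1, phase_times = NULL) {
  if (!length(phases)) abort("`phases` must be a non-empty list of 3D arrays")
  dims <- lapply(phases, dim)
  if (any(vapply(dims, length, 0L) != 3))
    abort("every phase must be a 3D array")
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    abort("all phases must have the same shape")
  if (is.null(phase_times)) phase_times <- seq_along(phases) - 1
  if (length(phase_times) != length(phases))
    abort("`phase_times` must have one entry per phase")
  if (phase_times[1] != 0)
    abort("the first phase must be end-expiration (phase_times[1] == 0)")
  if (any(diff(phase_times) <= 0))
    abort("`phase_times` must be strictly increasing")
  structure(
    list(phases = phases, voxel_size = voxel_size,
         phase_times = as.numeric(phase_times)),
    class = "volume4d"
  )
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d> %d phases of %s voxels (voxel %g), t = %s ms\n",
              length(x$phases), paste(dim(x$phases[[1]]), collapse = "x"),
              x$voxel_size,
              paste(signif(range(x$phase_times), 4), collapse = "..")))
  invisible(x)
}

#' @export
length.volume4d <- function(x) length(x$phases)

#' Number of phases in a 4D volume
#' @param x a [volume4d()]
#' @return integer phase count
#' @export
n_phases <- function(x) length(x$phases)
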