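#' Multiscale tubularity (vesselness) parameters
#'
#' Parameters of the Hessian-eigenvalue tubularity filter.  `alpha` controls
#' plate-vs-line discrimination, `beta` blob suppression, and `c` the
#' structureness (background) cutoff; when `c` is `NULL` it is set per scale
#' to half the maximum Hessian norm, the original convention.  Airways are
#' dark (air-filled) tubes, so `bright_on_dark = FALSE` by default.
#'
#' @param scales Gaussian kernel scales in voxels, positive increasing;
#'   default 10 geometrically spaced scales spanning 1-30
#' @param alpha plate-vs-line weight (dimensionless)
#' @param beta blob weight (dimensionless)
#' @param c structureness weight (intensity-scaled); `NULL` for per-scale
#'   automatic choice
#' @param bright_on_dark detect bright tubes instead of dark ones
#' @return an object of class `vesselness_params`
#' @export
vesselness_params <- function(scales = exp(seq(log(1), log(30),
                                               length.out = 10)),
                              alpha = 0.5, beta = 0.5, c = NULL,
                              bright_on_dark = FALSE) {
  if (!length(scales) || any(scales <= 0) || any(diff(scales) <= 0))
    abort("`scales` must be non-empty, positive and increasing")
  if (alpha <= 0 || beta <= 0) abort("`alpha` and `beta` must be positive")
  structure(
    list(scales = scales, alpha = alpha, beta = beta, c = c,
         bright_on_dark = bright_on_dark),
    class = "vesselness_params"
  )
}

#' Multiscale tubularity filter
#'
#' Per-voxel probability-like response that the voxel belongs to a tubular
#' structure: at each scale the scale-normalised Gaussian Hessian is
#' computed, its eigenvalues (|l1| <= |l2| <= |l3|) feed the classic
#' vesselness measure, and the response is the maximum over scales.  With
#' `bright_on_dark = FALSE` (default) dark tubes in bright surroundings are
#' selected (`l2, l3 > 0`).
#'
#' @param volume numeric 3D array
#' @param params a [vesselness_params()]
#' @return an object of class `tubularity`: list with `response` (array in
#'   \[0, 1\]) and `scale` (winning scale per voxel)
#' @export
multiscale_tubularity <- function(volume, params = vesselness_params()) {
  assert_volume3(volume)
  smax <- max(params$scales)
  if (min(dim(volume)) < 4 * smax)
    abort(sprintf(
      "volume (min dim %d) smaller than the largest kernel support (4 x scale %g)",
      min(dim(volume)), smax))
  d <- dim(volume)
  best <- array(0, d)
  wscale <- array(params$scales[1], d)
  a2 <- 2 * params$alpha^2
  b2 <- 2 * params$beta^2
  for (s in params$scales) {
    H <- gaussian_hessian3(volume, s)
    ev <- eig3_sym(H$zz, H$yy, H$xx, H$zy, H$zx, H$yx)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    ok <- if (params$bright_on_dark) (l2 < 0 & l3 < 0) else (l2 > 0 & l3 > 0)
    S2 <- l1^2 + l2^2 + l3^2
    cc <- if (is.null(params$c)) sqrt(max(S2)) / 2 else params$c
    if (cc <= 0) cc <- 1
    al3 <- abs(l3)
    al3[al3 == 0] <- Inf
    Ra2 <- (l2 / l3)^2
    Rb2 <- l1^2 / pmax(abs(l2 * l3), 1e-300)
    v <- (1 - exp(-Ra2 / a2)) * exp(-Rb2 / b2) * (1 - exp(-S2 / (2 * cc^2)))
    v[!ok] <- 0
    v[!is.finite(v)] <- 0
    upd <- v > best
    best[upd] <- v[upd]
    wscale[upd] <- s
  }
  structure(list(response = best, scale = wscale, params = params),
            class = "tubularity")
}

#' @export
print.tubularity <- function(x, ...) {
  cat(sprintf("<tubularity> %s, response in [%.3g, %.3g]\n",
              paste(dim(x$response), collapse = "x"),
              min(x$response), max(x$response)))
  invisible(x)
}

#' Flood-fill segmentation of the tubularity response
#'
#' The 26-connected component of `{response >= threshold}` containing the
#' seed.  The default threshold is Otsu's threshold of the positive
#' tubularity histogram.
#'
#' @param tubularity a [multiscale_tubularity()] result or a numeric array
#' @param seed seed voxel `c(z, y, x)` (0-based)
#' @param threshold response threshold; `NULL` for Otsu
#' @return logical 3D array mask
#' @export
flood_fill_segment <- function(tubularity, seed, threshold = NULL) {
  resp <- if (inherits(tubularity, "tubularity")) tubularity$response
          else tubularity
  assert_volume3(resp, "tubularity")
  if (is.null(threshold)) {
    pos <- resp[resp > 0]
    if (!length(pos)) abort("tubularity response is identically zero")
    threshold <- otsu_threshold(pos)
  }
  sv <- resp[seed[1] + 1, seed[2] + 1, seed[3] + 1]
  if (sv < threshold)
    abort(sprintf("seed response %.4g below threshold %.4g", sv, threshold))
  cpp_flood_fill26(resp >= threshold, dim(resp), as.integer(seed))
}
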