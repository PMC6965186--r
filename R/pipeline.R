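# End-to-end pipeline driver: phantom -> (recon) -> segmentation -> XV -> ATL.

default_config <- function() {
  list(
    seed = 1L,
    verbosity = 1L,
    phantom = list(
      grid_shape = c(96L, 96L, 96L), voxel_size = 1, tree_generations = 6L,
      tidal_fraction = 0.2, speckle_grain = 5, noise_sigma = 0.02,
      n_phases = 15L, base_tau = 80, center_taper = 0.4,
      defects = list(),
      ventilation = list(pip = 12, peep = 2, t_insp = 250, t_exp = 250,
                         respiratory_rate = 120, frame_rate = 30)
    ),
    recon = list(enabled = FALSE, r1 = 0.36, r2 = 3.0,
                 detector_pitch = 194e-6, detector_shape = c(128L, 128L),
                 projections_per_phase = 60L),
    segmentation = list(source = "image", scales = NULL, alpha = 0.5,
                        beta = 0.5, threshold = NULL, prune_factor = 2),
    xv = list(window = 32L, overlap = 0.5, smooth_sigma = 1,
              band_low = 0.01, band_high = 0.25, peak_quality_min = 1.2,
              fill_invalid = TRUE, refine = "gaussian"),
    atl = list(start = "protocol", method = "crossing",
               quadrature = "voxel")
  )
}

check_keys <- function(user, defaults, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    abort(sprintf("unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" in ", path) else "",
                  paste(extra, collapse = ", ")))
  for (k in names(user)) {
    if (k %in% c("defects", "scales", "threshold", "detector_shape",
                 "grid_shape"))
      next
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      check_keys(user[[k]], defaults[[k]], paste0(path, k, "/"))
  }
  invisible(TRUE)
}

merge_config <- function(user, defaults) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
        !k %in% c("defects", "detector_shape", "grid_shape", "scales"))
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]])
    else defaults[k] <- list(user[[k]]) # NULL-safe: keeps the key
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds a validated pipeline configuration by merging overrides into the
#' documented defaults.  Unknown keys are rejected.  The configuration
#' round-trips through YAML unchanged via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param ... named overrides of the default sections (`seed`, `verbosity`,
#'   `phantom`, `recon`, `segmentation`, `xv`, `atl`); see
#'   `pipeline_config()` for all keys and defaults
#' @return an object of class `pipeline_config` (nested named list)
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defaults <- default_config()
  check_keys(user, defaults)
  cfg <- merge_config(user, defaults)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path
#' @param config a [pipeline_config()]
#' @return `read_pipeline_config`: a validated [pipeline_config()];
#'   `write_pipeline_config`: the path, invisibly
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_phantom_spec <- function(cfg) {
  ph <- cfg$phantom
  vent <- do.call(ventilation_protocol, ph$ventilation)
  defects <- lapply(ph$defects, function(d) do.call(defect_spec, d))
  phantom_spec(
    grid_shape = ph$grid_shape, voxel_size = ph$voxel_size,
    tree_generations = ph$tree_generations,
    tidal_fraction = ph$tidal_fraction, speckle_grain = ph$speckle_grain,
    noise_sigma = ph$noise_sigma, n_phases = ph$n_phases,
    base_tau = ph$base_tau, center_taper = ph$center_taper,
    defects = defects, ventilation = vent, seed = cfg$seed
  )
}

#' Run the full synthetic 4DxV pipeline
#'
#' Executes the selected stages in order — phantom generation, optional
#' projection/reconstruction round-trip, airway segmentation, XV tracking,
#' ATL analysis — writing every stage's outputs plus a `manifest.yaml`
#' (package version, configuration and its hash, per-stage summary
#' statistics).  Fully reproducible for a fixed config seed; a stage
#' failure halts the run with the stage name and cause.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param stages which stages to run after the phantom
#' @return the manifest (named list), invisibly
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("segment", "xv", "atl")) {
  if (!inherits(config, "pipeline_config")) abort("invalid config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vlog <- function(...) if (config$verbosity >= 1) message(sprintf(...))
  manifest <- list(
    package = as.character(utils::packageVersion("lung4dxv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    stages = list()
  )
  run_stage <- function(name, fn) {
    vlog("[%s] running", name)
    tryCatch(fn(), error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  spec <- config_phantom_spec(config)
  ph <- run_stage("phantom", function() simulate_breath_series(spec))
  write_volume4d(ph$volumes, file.path(out_dir, "volumes"))
  write_tree_vtk(ph$tree, file.path(out_dir, "tree_truth.vtk"))
  readr::write_csv(ph$truth$regional_volumes,
                   file.path(out_dir, "truth_regional_volumes.csv"))
  readr::write_csv(tidy(ph$tree), file.path(out_dir, "tree_truth.csv"))
  manifest$stages$phantom <- list(
    grid = paste(spec$grid_shape, collapse = "x"),
    n_phases = spec$n_phases, n_segments = nrow(ph$tree$segments),
    peak_tidal_volume_truth = max(ph$truth$total$volume))
  vlog("[phantom] %d phases of %s, %d segments", spec$n_phases,
       paste(spec$grid_shape, collapse = "x"), nrow(ph$tree$segments))

  if (config$recon$enabled) {
    rc <- config$recon
    geom <- recon_geometry(rc$r1, rc$r2, rc$detector_pitch,
                           rc$detector_shape)
    sched <- gating_schedule(spec$ventilation$frame_rate,
                             spec$ventilation$respiratory_rate)
    nfr <- rc$projections_per_phase * spec$n_phases
    set.seed(derive_seed(config$seed, 7L))
    angles <- (seq_len(nfr) - 1) * 360 / nfr
    proj <- run_stage("recon", function()
      forward_project(ph$volumes, geom, angles, sched))
    recon <- run_stage("recon", function()
      reconstruct_4d(proj, sched, geom, spec$grid_shape))
    write_volume4d(recon, file.path(out_dir, "recon"))
    manifest$stages$recon <- list(
      n_projections = nfr, per_phase = rc$projections_per_phase)
    vlog("[recon] %d projections -> %d phase volumes", nfr, spec$n_phases)
  }

  tree <- ph$tree
  if ("segment" %in% stages) {
    sg <- config$segmentation
    if (identical(sg$source, "image")) {
      scales <- if (is.null(sg$scales)) {
        rmax <- max(vapply(tree$segments$points, function(p) max(p[, 4]), 0))
        exp(seq(log(1), log(max(2, rmax)), length.out = 6))
      } else sg$scales
      vp <- vesselness_params(scales = scales, alpha = sg$alpha,
                              beta = sg$beta)
      seedvox <- round(tree$segments$points[[1]][2, 1:3])
      tree <- run_stage("segment", function()
        segment_airways(ph$volumes, vp, seedvox, threshold = sg$threshold,
                        prune_factor = sg$prune_factor))
    }
    write_tree_vtk(tree, file.path(out_dir, "tree.vtk"))
    readr::write_csv(tidy(tree), file.path(out_dir, "tree.csv"))
    g <- glance(tree)
    manifest$stages$segment <- list(
      source = sg$source, n_segments = g$n_segments,
      n_terminals = g$n_terminals, max_generation = g$max_generation)
    vlog("[segment] %d segments to generation %d", g$n_segments,
         g$max_generation)
  }

  track <- NULL
  if ("xv" %in% stages) {
    xc <- config$xv
    params <- xv_params(window = xc$window, overlap = xc$overlap,
                        smooth_sigma = xc$smooth_sigma,
                        band_low = xc$band_low, band_high = xc$band_high,
                        peak_quality_min = xc$peak_quality_min,
                        fill_invalid = xc$fill_invalid, refine = xc$refine)
    track <- run_stage("xv", function()
      track_breath(ph$volumes, params, ph$lung_mask))
    for (t in seq_along(track$fields))
      write_field_csv(track$fields[[t]],
                      file.path(out_dir, sprintf("field_%02d.csv", t - 1)))
    nval <- vapply(track$fields, function(f) sum(f$valid), 0L)
    manifest$stages$xv <- list(
      n_intervals = length(track$fields),
      nodes = nrow(track$fields[[1]]),
      median_valid = as.numeric(median(nval)))
    vlog("[xv] %d interval fields, %d nodes, median %d valid",
         length(track$fields), nrow(track$fields[[1]]), median(nval))
  }

  if ("atl" %in% stages) {
    if (is.null(track)) abort("pipeline stage 'atl' failed: requires xv")
    regional <- run_stage("atl", function() {
      if (identical(config$atl$quadrature, "voxel")) {
        labels <- assign_regions(ph$lung_mask, tree)
        regional_volumes(track$expansions, labels, track$phase_times,
                         spec$voxel_size, lung_mask = ph$lung_mask)
      } else {
        assignment <- assign_regions(track$expansions[[1]], tree)
        elem <- node_cell_volumes(track$expansions[[1]], ph$lung_mask,
                                  spec$voxel_size)
        regional_volumes(track$expansions, assignment, track$phase_times,
                         spec$voxel_size, elem)
      }
    })
    flow <- run_stage("atl", function() flow_sum(tree, regional))
    taus <- run_stage("atl", function()
      expiratory_time_constant(flow, spec$ventilation,
                               method = config$atl$method,
                               start = config$atl$start))
    readr::write_csv(
      dplyr::rename(taus, tau_ms = "tau"),
      file.path(out_dir, "atl_time_constants.csv"))
    readr::write_csv(flow, file.path(out_dir, "atl_branch_flow.csv"))
    write_tree_vtk(tree, file.path(out_dir, "tree_tau.vtk"),
                   values = taus[, c("id", "tau")])
    g <- glance(flow)
    manifest$stages$atl <- list(
      n_segments = g$n_segments, tidal_volume = g$tidal_volume,
      median_tau = as.numeric(median(taus$tau[taus$valid])))
    vlog("[atl] tidal volume %.4g, median tau %.1f ms", g$tidal_volume,
         median(taus$tau[taus$valid]))
  }

  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
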