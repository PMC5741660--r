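# Pipeline configuration and end-to-end composition:
# denoise -> feature maps -> trajectory -> kinematics -> morphometry.

default_config <- function() {
  list(
    imageproc = list(denoise_sigma_px = 1, n_scales = 4, n_orientations = 6,
                     min_wavelength = 3, scale_multiplier = 2.1,
                     filter_bandwidth = 0.55, noise_k = 2, epsilon = 1e-4,
                     pc_threshold = 0.2, min_object_px = 20,
                     background_percentile = 5),
    tracking = list(search_radius_px = 25, wave_factor = 1.5,
                    soma_exclude_um = 12, gc_exclude_um = 12,
                    max_gap_frames = 2),
    kinematics = list(merge_tolerance_um = 3, min_track_frames = 3,
                      min_pull_amplitude_um = 5, approach_window_um = 20,
                      window_min = 60, complete_only = FALSE),
    morphometry = list(threshold_policy = "fraction", threshold_fraction = 0.5,
                       window_px = 40, response_window_min = 5,
                       loss_at_min = 45),
    seed = 1L,
    verbosity = 1L
  )
}

#' Load (or build) a pipeline configuration
#'
#' Reads a YAML file with per-module blocks and merges it over the documented
#' defaults; unknown keys are rejected.
#'
#' @param path YAML path, or NULL for the defaults.
#' @param overrides named nested list merged last.
#' @return configuration list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  merge_block <- function(cfg, user, where = "") {
    for (k in names(user)) {
      if (!k %in% names(cfg))
        wt_stop(sprintf("unknown config key '%s%s'", where, k),
                "validation_error", field = k)
      if (is.list(cfg[[k]]) && is.list(user[[k]]))
        cfg[[k]] <- merge_block(cfg[[k]], user[[k]], paste0(where, k, "."))
      else cfg[[k]] <- user[[k]]
    }
    cfg
  }
  if (!is.null(path)) cfg <- merge_block(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_block(cfg, overrides)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline on a movie
#'
#' Executes denoise, phase-congruency feature maps, trajectory tracking,
#' kinematics and (optionally) growth-cone morphometry in order, writes the
#' CSV/JSON outputs and a machine-readable run manifest, and returns the
#' result bundle. Re-running with the same configuration and inputs
#' reproduces the numeric outputs bit-identically.
#'
#' @param stack a \code{\link{calibrated_stack}} (or TIFF path readable by
#'   \code{\link{read_stack}}).
#' @param seeds seed annotation list (or JSON path).
#' @param config a \code{\link{pipeline_config}} (or YAML path or NULL).
#' @param out_dir output directory, or NULL to skip writing.
#' @param morphometry run the GC area time course from the edge seed.
#' @return list of class \code{pipeline_result}: trajectory, events, summary,
#'   pulling events, areas (or NULL), gc_response (or NULL), manifest.
#' @export
run_pipeline <- function(stack, seeds, config = NULL, out_dir = NULL,
                         morphometry = FALSE) {
  if (is.character(stack)) stack <- read_stack(stack)
  if (is.character(seeds)) seeds <- read_seeds(seeds)
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  ip <- cfg$imageproc; tk <- cfg$tracking; kin <- cfg$kinematics
  say <- function(...) if (cfg$verbosity > 0) message(sprintf(...))

  pcp <- pc_params(ip$n_scales, ip$n_orientations, ip$min_wavelength,
                   ip$scale_multiplier, ip$filter_bandwidth, ip$noise_k,
                   ip$epsilon, ip$pc_threshold)
  n <- dim(stack$frames)[3]
  say("stage feature_maps: %d frame(s)", n)
  maps <- vector("list", n)
  for (f in seq_len(n)) {
    maps[[f]] <- tryCatch(
      make_feature_map(stack$frames[, , f],
                       pcp, ip$min_object_px, ip$background_percentile),
      error = function(e) wt_stop(
        sprintf("stage feature_maps failed at frame %d: %s", f,
                conditionMessage(e)), "stage_error"))
  }

  say("stage tracking")
  trajectory <- tryCatch(
    track_trajectory(stack, maps, seeds,
                     search_radius_px = tk$search_radius_px,
                     wave_factor = tk$wave_factor,
                     denoise_sigma_px = ip$denoise_sigma_px,
                     soma_exclude_um = tk$soma_exclude_um,
                     gc_exclude_um = tk$gc_exclude_um,
                     max_gap_frames = tk$max_gap_frames),
    error = function(e) wt_stop(
      paste("stage tracking failed:", conditionMessage(e)), "stage_error"))

  say("stage kinematics")
  events <- wave_events(trajectory, kin$merge_tolerance_um,
                        kin$min_track_frames)
  summary <- summarize_kinematics(trajectory, kin$complete_only)
  pulls <- detect_pulling_events(trajectory, kin$min_pull_amplitude_um,
                                 kin$approach_window_um)

  areas <- NULL; gcr <- NULL
  if (morphometry) {
    say("stage morphometry")
    mo <- cfg$morphometry
    areas <- region_area_timecourse(stack, seeds$edge_point,
                                    threshold_policy = mo$threshold_policy,
                                    threshold_fraction = mo$threshold_fraction,
                                    window_px = mo$window_px)
    merges <- events$end_time_s[events$completed]
    if (length(merges))
      gcr <- gc_wave_response(areas, merges, mo$response_window_min,
                              mo$loss_at_min)
  }

  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   n_frames = n, package_version =
                     as.character(utils::packageVersion("wavetrack")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(trajectory, file.path(out_dir, "trajectory.csv"))
    utils::write.csv(events, file.path(out_dir, "wave_events.csv"),
                     row.names = FALSE)
    utils::write.csv(pulls, file.path(out_dir, "pulling_events.csv"),
                     row.names = FALSE)
    if (!is.null(areas))
      utils::write.csv(as.data.frame(areas), file.path(out_dir, "areas.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(trajectory = trajectory, events = events, summary = summary,
                 pulling_events = pulls, areas = areas, gc_response = gcr,
                 manifest = manifest, config = cfg),
            class = "pipeline_result")
}
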