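# End-to-end pipeline: (simulate | load) -> register -> detect -> link ->
# kymograph -> kinetics, with YAML configuration and a provenance record.

.pipeline_schema <- list(
  top = c("input", "simulation", "calibration", "path", "registration",
          "detection", "linking", "kinetics", "output_dir", "seed"),
  calibration = c("pixel_size", "frame_interval"),
  registration = c("enabled", "reference", "chained", "window",
                   "smooth_sigma"),
  detection = c("psf_sigma_px", "min_separation", "threshold_sd",
                "window_radius"),
  linking = c("max_jump", "max_gap"),
  kinetics = c("sigma_loc", "min_frames", "v_min", "r2_min", "dwell_min",
               "min_duration", "min_r2"))

#' Validate a pipeline configuration
#'
#' Checks required fields (calibration with positive `pixel_size` and
#' `frame_interval`; either an `input` movie path that exists or a
#' `simulation` block), rejects unknown keys, and fills defaults.
#'
#' @param config a named list (e.g. from [yaml::read_yaml()]).
#' @return the validated configuration with defaults filled in.
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), .pipeline_schema$top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (blk in c("calibration", "registration", "detection", "linking",
                "kinetics")) {
    unknown <- setdiff(names(config[[blk]]), .pipeline_schema[[blk]])
    if (length(unknown))
      stop("unknown key(s) in ", blk, ": ",
           paste(unknown, collapse = ", "))
  }
  cal <- config$calibration
  if (is.null(cal$pixel_size))
    stop("configuration is missing required field: calibration.pixel_size")
  if (is.null(cal$frame_interval))
    stop("configuration is missing required field: ",
         "calibration.frame_interval")
  if (cal$pixel_size <= 0 || cal$frame_interval <= 0)
    stop("calibration values must be positive")
  if (is.null(config$input) && is.null(config$simulation))
    stop("configuration needs either an input movie or a simulation block")
  if (!is.null(config$input) && !file.exists(config$input))
    stop("input movie does not exist: ", config$input)
  defaults <- list(
    registration = list(enabled = TRUE, reference = "first",
                        chained = TRUE, window = TRUE, smooth_sigma = 1),
    detection = list(psf_sigma_px = 1, min_separation = 3,
                     threshold_sd = 5, window_radius = 3),
    linking = list(max_jump = 500, max_gap = 2),
    kinetics = list(sigma_loc = 30, min_frames = 8, v_min = 20,
                    r2_min = 0.8, dwell_min = 2, min_duration = 0,
                    min_r2 = 0))
  for (blk in names(defaults))
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       config[[blk]] %||% list())
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

# Build the simulation inputs declared in a config's simulation block.
.build_simulation <- function(config) {
  sim <- config$simulation
  geo <- stereocilium_geometry(unlist(sim$geometry$base_point),
                               unlist(sim$geometry$tip_point),
                               sim$geometry$radius %||% 0)
  cfg_args <- sim$config %||% list()
  cfg_args$pixel_size <- config$calibration$pixel_size
  cfg_args$frame_interval <- config$calibration$frame_interval
  cfg_args$seed <- config$seed
  if (!is.null(cfg_args$drift)) {
    cfg_args$drift <- do.call(drift_model, lapply(cfg_args$drift, unlist))
  }
  scfg <- do.call(sim_config, cfg_args)
  ems <- lapply(sim$emitters, function(e) {
    emitter(do.call(motility_model, e$motility %||% list()),
            do.call(photophysics_model, e$photophysics %||% list()),
            start = e$start %||% 0)
  })
  simulate_movie(scfg, geo, ems)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> drift correction -> punctum detection ->
#' intensity measurement -> track linking -> axial projection -> kymograph
#' -> per-track kinetics, and optionally writes every result to
#' `output_dir` (drift trace CSV, detections CSV, tracks CSV, kymograph
#' TIFF/PNG, kinetics CSV, summary + provenance JSON).
#'
#' @param config pipeline configuration (named list or path to a YAML
#'   file); see [validate_pipeline_config()].
#' @param write write result files to `config$output_dir`.
#' @return a result bundle: list with `movie`, `truth` (when simulated),
#'   `drift`, `detections`, `tracks`, `kymograph`, `kinetics`,
#'   `velocity_summary` and `provenance`.
#' @export
run_pipeline <- function(config, write = !is.null(config$output_dir)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  cal <- config$calibration

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- .build_simulation(config)
    movie <- sim$movie; truth <- sim$truth
  } else {
    movie <- read_movie_tiff(config$input, cal$pixel_size,
                             cal$frame_interval)
  }

  drift <- NULL
  if (isTRUE(config$registration$enabled) && n_frames(movie) >= 2) {
    reg <- config$registration
    cc <- tryCatch(
      correct_movie(movie, reference = reg$reference,
                    chained = reg$chained, window = reg$window,
                    smooth_sigma = reg$smooth_sigma),
      error = function(e) stop("registration stage failed: ",
                               conditionMessage(e)))
    movie <- cc$movie; drift <- cc$trace
  }

  det <- config$detection
  detections <- tryCatch(
    detect_movie(movie, psf_sigma_px = det$psf_sigma_px,
                 min_separation = det$min_separation,
                 threshold_sd = det$threshold_sd),
    error = function(e) stop("detection stage failed: ",
                             conditionMessage(e)))
  detections <- measure_intensities(movie, detections,
                                    window_radius = det$window_radius)

  path <- if (!is.null(config$path)) {
    organelle_path(do.call(rbind, lapply(config$path$points, unlist)),
                   half_width = config$path$half_width %||% 2,
                   pixel_size = cal$pixel_size)
  } else if (!is.null(truth)) {
    g <- truth$geometry
    organelle_path(rbind(g$base_point, g$tip_point) / cal$pixel_size,
                   half_width = 2, pixel_size = cal$pixel_size)
  } else stop("configuration needs a path block for recorded movies")

  lnk <- config$linking
  tracks <- link_tracks(detections, pixel_size = cal$pixel_size,
                        max_jump = lnk$max_jump, max_gap = lnk$max_gap)
  tracks <- project_to_axis(tracks, path,
                            frame_interval = cal$frame_interval)

  kymo <- tryCatch(build_kymograph(movie, path),
                   error = function(e) stop("kymograph stage failed: ",
                                            conditionMessage(e)))

  kin <- config$kinetics
  kinetics <- track_kinetics(tracks, sigma_loc = kin$sigma_loc,
                             min_frames = kin$min_frames,
                             v_min = kin$v_min, r2_min = kin$r2_min,
                             dwell_min = kin$dwell_min)
  vsum <- summarize_velocities(
    kinetics[kinetics$mode == "processive" & !is.na(kinetics$v), ,
             drop = FALSE],
    min_duration = kin$min_duration, min_r2 = kin$min_r2)

  provenance <- list(package = "kymotor",
                     version = as.character(utils::packageVersion("kymotor")),
                     seed = config$seed,
                     config_hash = config_hash(config),
                     n_frames = n_frames(movie))
  bundle <- list(movie = movie, truth = truth, drift = drift,
                 detections = detections, tracks = tracks,
                 kymograph = kymo, kinetics = kinetics,
                 velocity_summary = vsum, provenance = provenance)
  if (write) write_bundle(bundle, config)
  bundle
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; recorded in every output's
#' provenance so results can be traced to the exact parameters.
#'
#' @param config a configuration list.
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Write a pipeline result bundle to a directory
#'
#' @param bundle result of [run_pipeline()].
#' @param config the validated configuration (supplies `output_dir`).
#' @export
write_bundle <- function(bundle, config) {
  out <- config$output_dir
  if (is.null(out)) stop("config$output_dir is not set")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$drift))
    write_drift_trace(bundle$drift, file.path(out, "drift_trace.csv"))
  write_detections(bundle$detections, file.path(out, "detections.csv"))
  write_tracks(bundle$tracks, file.path(out, "tracks.csv"))
  write_kymograph(bundle$kymograph,
                  tiff_path = file.path(out, "kymograph.tif"),
                  png_path = file.path(out, "kymograph.png"))
  utils::write.csv(bundle$kinetics, file.path(out, "kinetics.csv"),
                   row.names = FALSE)
  vs <- bundle$velocity_summary
  jsonlite::write_json(
    list(provenance = bundle$provenance,
         velocity = list(mean = vs$mean, sd = vs$sd, n = vs$n),
         modes = as.list(table(bundle$kinetics$mode))),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  if (!is.null(bundle$truth))
    write_ground_truth(bundle$truth,
                       json_path = file.path(out, "ground_truth.json"),
                       csv_path = file.path(out, "ground_truth.csv"))
  invisible(out)
}
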