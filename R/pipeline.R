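#' Pipeline configuration
#'
#' One configuration object for a full run of the pipeline. Acquisition
#' limits follow the capture software: sampling interval 3-60 s,
#' duration 3-120 min.
#'
#' @param interval_s Sampling interval in seconds (3-60; default 5).
#' @param duration_s Session duration in seconds (180-7200; default
#'   3600).
#' @param n_rows,n_cols LED grid (default 10 x 20).
#' @param image_width,image_height Frame geometry (default 320 x 240).
#' @param seed Master seed; stage seeds are derived from it.
#' @param noise_sd,gain_sdlog,jitter_sd,psf_sigma,diffuser_sigma,background_level
#'   Simulator parameters, see [sensor_population()] and [led_grid()].
#' @param common_signal Common-signal strength of the gain-test session
#'   (signal units, default 0.5).
#' @param window Heatmap averaging window (default 20).
#' @param min_separation Peak-detection separation floor in px.
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the map, gain matrix, series and heatmap there.
#' @return A `ppc_pipeline_config`.
#' @export
pipeline_config <- function(interval_s = 5, duration_s = 3600,
                            n_rows = 10L, n_cols = 20L,
                            image_width = 320L, image_height = 240L,
                            seed = 1L, noise_sd = 0.005,
                            gain_sdlog = 0.1, jitter_sd = 1,
                            psf_sigma = 1.5, diffuser_sigma = 1,
                            background_level = 8, common_signal = 0.5,
                            window = 20L, min_separation = 6,
                            out_dir = NULL) {
  if (interval_s < 3 || interval_s > 60)
    ppc_stop("invalid_config",
             "interval_s must lie in the supported 3-60 s range (got %g)",
             interval_s)
  if (duration_s < 180 || duration_s > 7200)
    ppc_stop("invalid_config",
             "duration_s must lie in the supported 180-7200 s range (got %g)",
             duration_s)
  structure(list(interval_s = interval_s, duration_s = duration_s,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 gain_sdlog = gain_sdlog, jitter_sd = jitter_sd,
                 psf_sigma = psf_sigma, diffuser_sigma = diffuser_sigma,
                 background_level = background_level,
                 common_signal = common_signal,
                 window = as.integer(window),
                 min_separation = min_separation, out_dir = out_dir),
            class = "ppc_pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose fields match the [pipeline_config()]
#'   arguments.
#' @return A `ppc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ppc_stop("invalid_config", "no such file: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(j), known)
  if (length(bad))
    ppc_stop("invalid_config", "unknown config fields: %s",
             paste(bad, collapse = ", "))
  do.call(pipeline_config, j)
}

#' Run the full pipeline on a simulated rig
#'
#' Executes the whole chain with ground truth available at every stage:
#' build the rig (sensor population + LED grid), render the all-on
#' calibration frame and detect the vector map, run a common-signal
#' session and derive the gain matrix, run the experiment session,
#' decode and calibrate it, and reduce it to the subject's heatmap.
#' Returns a machine-readable report; identical configurations and
#' seeds give identical reports (apart from the wall-clock field).
#'
#' @param config A `ppc_pipeline_config`.
#' @param calibration_frames Number of frames of the common-signal
#'   session used for `M_test` (default 20).
#' @return A `ppc_run_report`: list with `n_frames`, `n_channels`,
#'   `n_samples`, `wiring_connections`, `detected_peaks`,
#'   `max_center_error_px`, `clipped_cells`, `heatmap`, `series`,
#'   `gain`, `map`, `file_hashes` (when `out_dir` is set) and
#'   `started`.
#' @export
run_pipeline <- function(config, calibration_frames = 20L) {
  if (!inherits(config, "ppc_pipeline_config"))
    ppc_stop("invalid_config", "'config' must come from pipeline_config()")
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  stage <- function(name, expr) {
    tryCatch(expr, ppc_error = function(e) {
      ppc_stop("pipeline", "stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  layout <- layout_spec(config$n_rows, config$n_cols)
  grid <- stage("rig", led_grid(
    config$n_rows, config$n_cols, config$image_width, config$image_height,
    jitter_sd = config$jitter_sd, psf_sigma = config$psf_sigma,
    diffuser_sigma = config$diffuser_sigma,
    background_level = config$background_level, seed = config$seed))
  pop <- stage("rig", sensor_population(
    config$n_rows * config$n_cols, gain_sdlog = config$gain_sdlog,
    noise_sd = config$noise_sd, seed = config$seed + 1L))

  # vector-map calibration on the all-on frame
  map <- stage("map", {
    fr <- calibration_frame(grid)
    assign_labels(detect_led_centers(fr, length(pop$gains),
                                     min_separation = config$min_separation,
                                     smooth_sigma = config$psf_sigma / 2),
                  layout)
  })
  nn <- nearest_center_errors(map, grid)

  # gain calibration from a short common-signal session
  gain <- stage("gain", {
    cal_cfg <- session_config(config$n_rows, config$n_cols,
                              duration_s = calibration_frames * config$interval_s,
                              interval_s = config$interval_s,
                              image_width = config$image_width,
                              image_height = config$image_height,
                              seed = config$seed + 2L)
    cal <- simulate_session(cal_cfg, pop, grid,
                            common_signal = config$common_signal)
    compute_gain(session_mean_matrix(decode_sequence(cal$frames, map, layout)))
  })

  # experiment session -> decode -> calibrate -> heatmap
  cfg <- session_config(config$n_rows, config$n_cols,
                        duration_s = config$duration_s,
                        interval_s = config$interval_s,
                        image_width = config$image_width,
                        image_height = config$image_height,
                        seed = config$seed + 3L)
  ses <- stage("simulate", simulate_session(cfg, pop, grid))
  series <- stage("decode", decode_sequence(ses$frames, map, layout))
  clipped <- 0L
  calibrated <- stage("gain", {
    mats <- lapply(series$matrices, function(m) {
      out <- apply_gain(m, gain)
      clipped <<- clipped + attr(out, "n_clipped")
      out
    })
    signal_series(mats, series$interval_s)
  })
  hm <- stage("heatmap", average_encoded_matrix(
    calibrated, window = min(config$window, length(calibrated$matrices)),
    subject_id = sprintf("sim-%d", config$seed)))

  hashes <- NULL
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    save_vector_map(map, file.path(d, "map.csv"))
    save_gain_matrix(gain, file.path(d, "gain.csv"))
    write_series(calibrated, file.path(d, "series.csv"), layout)
    save_heatmap(hm, file.path(d, "heatmap.csv"))
    save_heatmap(hm, file.path(d, "heatmap.png"))
    files <- file.path(d, c("map.csv", "gain.csv", "series.csv",
                            "heatmap.csv", "heatmap.png"))
    hashes <- tools::md5sum(files)
  }
  structure(list(
    n_frames = length(ses$frames),
    n_channels = n_channels(cfg),
    n_samples = count_samples(n_channels(cfg), length(ses$frames)),
    wiring_connections = wiring_connections(16L, n_channels(cfg)),
    detected_peaks = nrow(map),
    max_center_error_px = max(nn),
    clipped_cells = clipped,
    heatmap = hm, series = calibrated, gain = gain, map = map,
    layout = layout, truth = ses$truth,
    file_hashes = hashes, started = started
  ), class = "ppc_run_report")
}

# distance of each map entry to its nearest true centre
nearest_center_errors <- function(map, grid) {
  ctr <- grid$true_centers
  vapply(seq_len(nrow(map)), function(k) {
    dx <- ctr[, 1] - map$x[k]; dy <- ctr[, 2] - map$y[k]
    sqrt(min(dx * dx + dy * dy))
  }, numeric(1))
}

#' @export
print.ppc_run_report <- function(x, ...) {
  cat("photon-pixel pipeline run\n")
  cat(sprintf("  frames decoded      : %d\n", x$n_frames))
  cat(sprintf("  channels            : %d\n", x$n_channels))
  cat(sprintf("  scalar samples (Ns) : %s\n",
              format(x$n_samples, big.mark = ",")))
  cat(sprintf("  wiring connections  : %d\n", x$wiring_connections))
  cat(sprintf("  LED centres detected: %d (max error %.2f px)\n",
              x$detected_peaks, x$max_center_error_px))
  cat(sprintf("  clipped cells       : %d\n", x$clipped_cells))
  invisible(x)
}
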