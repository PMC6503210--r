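#' Sensor brightness response
#'
#' Monotone saturating response of the amplifier chain: brightness grows
#' linearly as `gain * signal / saturation_level` and clamps at 1.0. Any
#' signal at or above `saturation_level` drives the LED to full
#' brightness regardless of gain. The true luminance-vs-current curve of
#' the LEDs is not modelled beyond this monotone saturating shape.
#'
#' @param signal Signal in signal units (vector allowed; negative values
#'   floor at 0).
#' @param gain Multiplicative sensor gain (> 0; scalar or per-element).
#' @param saturation_level Signal units at which brightness reaches 1.0
#'   (> 0).
#' @return Brightness fraction(s) in `[0, 1]`.
#' @examples
#' sensor_response(0, 1, 1)    # 0
#' sensor_response(2, 0.7, 1)  # 1: at/above saturation
#' @export
sensor_response <- function(signal, gain, saturation_level) {
  if (any(!is.finite(saturation_level)) || any(saturation_level <= 0))
    ppc_stop("invalid_config", "'saturation_level' must be > 0")
  if (any(!is.finite(gain)) || any(gain <= 0))
    ppc_stop("invalid_config", "'gain' must be > 0")
  b <- pmin(1, pmax(0, signal * gain / saturation_level))
  b[signal >= saturation_level] <- 1
  b
}

#' Render one camera frame of the LED matrix
#'
#' Draws each LED as an isotropic Gaussian spot of total sd
#' `sqrt(psf_sigma^2 + diffuser_sigma^2)` at its true (jittered) centre,
#' with peak amplitude `background_level + brightness * (255 -
#' background_level)`, on a dark background. Overlapping spots add.
#' White LEDs: the three RGB channels are identical before noise.
#' Optional additive Gaussian pixel noise (per channel) is clipped to
#' `[0, 255]` and the frame is quantised to 8-bit.
#'
#' @param brightness Per-channel brightness fractions in `[0, 1]`,
#'   length `n_rows * n_cols` in row-major LED order.
#' @param grid A [led_grid()].
#' @param cfg A [session_config()] (frame dimensions must match the grid).
#' @param noise_sd Pixel noise as a fraction of full scale (default 0).
#' @param index,timestamp Frame index (0-based) and acquisition time in
#'   seconds from session start.
#' @return A `ppc_frame`: list with `pixels` (height x width x 3 integer
#'   array, 0-255), `index` and `timestamp`.
#' @export
render_frame <- function(brightness, grid, cfg = NULL, noise_sd = 0,
                         index = 0L, timestamp = 0) {
  w <- grid$image_width; h <- grid$image_height
  if (!is.null(cfg) && (cfg$image_width != w || cfg$image_height != h))
    ppc_stop("render", "frame geometry of cfg (%dx%d) does not match grid (%dx%d)",
             cfg$image_width, cfg$image_height, w, h)
  n <- grid$n_rows * grid$n_cols
  if (length(brightness) != n)
    ppc_stop("render", "brightness has length %d, expected %d channels",
             length(brightness), n)
  ctr <- grid$true_centers
  if (any(ctr[, 1] < 0 | ctr[, 1] > w - 1 | ctr[, 2] < 0 | ctr[, 2] > h - 1))
    ppc_stop("render", "a spot centre lies outside the image bounds")
  bg <- grid$background_level
  sigma <- sqrt(grid$psf_sigma^2 + grid$diffuser_sigma^2)
  r <- ceiling(4 * sigma)
  canvas <- matrix(bg, nrow = h, ncol = w)
  amp <- brightness * (255 - bg)
  for (k in seq_len(n)) {
    if (amp[k] <= 0) next
    xc <- ctr[k, 1]; yc <- ctr[k, 2]
    x0 <- max(0, floor(xc) - r); x1 <- min(w - 1, ceiling(xc) + r)
    y0 <- max(0, floor(yc) - r); y1 <- min(h - 1, ceiling(yc) + r)
    gx <- exp(-((x0:x1) - xc)^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - yc)^2 / (2 * sigma^2))
    canvas[(y0:y1) + 1L, (x0:x1) + 1L] <-
      canvas[(y0:y1) + 1L, (x0:x1) + 1L] + amp[k] * outer(gy, gx)
  }
  px <- array(canvas, dim = c(h, w, 3))
  if (noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), sd = noise_sd * 255), dim = dim(px))
  px <- round(pmin(pmax(px, 0), 255))
  storage.mode(px) <- "integer"
  structure(list(pixels = px, index = as.integer(index),
                 timestamp = timestamp),
            class = "ppc_frame")
}

#' Signal dynamics of a synthetic subject
#'
#' Per-channel electrodermal-like dynamics over a session: a constant
#' baseline drawn uniformly from `baseline_range`, a slow Gaussian
#' random-walk drift, and optional step responses at configurable times
#' (emulating the two oral glucose doses at 15 and 30 min as signal
#' perturbations only; no metabolic model).
#'
#' @param baseline_range Range of per-channel baselines in signal units.
#' @param drift_sd Random-walk innovation sd per frame.
#' @param step_times_s Times (s) of step responses; `numeric(0)` for none.
#' @param step_amplitude Step height in signal units.
#' @return A `ppc_signal_dynamics` parameter list.
#' @export
signal_dynamics <- function(baseline_range = c(0.35, 0.65),
                            drift_sd = 0.002,
                            step_times_s = c(900, 1800),
                            step_amplitude = 0.08) {
  structure(list(baseline_range = baseline_range, drift_sd = drift_sd,
                 step_times_s = step_times_s,
                 step_amplitude = step_amplitude),
            class = "ppc_signal_dynamics")
}

simulate_signals <- function(cfg, dynamics, common_signal = NULL) {
  nf <- n_frames(cfg)
  nc <- n_channels(cfg)
  if (nf == 0L) return(matrix(numeric(0), nrow = nc, ncol = 0))
  if (!is.null(common_signal)) {
    if (length(common_signal) == 1L)
      common_signal <- rep(common_signal, nf)
    if (length(common_signal) != nf)
      ppc_stop("invalid_config",
               "common_signal must be scalar or length %d", nf)
    return(matrix(rep(common_signal, each = nc), nrow = nc, ncol = nf))
  }
  base <- stats::runif(nc, dynamics$baseline_range[1], dynamics$baseline_range[2])
  drift <- matrix(stats::rnorm(nc * nf, sd = dynamics$drift_sd), nc, nf)
  drift <- t(apply(drift, 1, cumsum))
  if (nf == 1L) drift <- matrix(drift, nc, nf)
  sig <- base + drift
  ts <- (seq_len(nf) - 1L) * cfg$interval_s
  for (st in dynamics$step_times_s) {
    on <- ts >= st
    if (any(on)) sig[, on] <- sig[, on] + dynamics$step_amplitude
  }
  sig
}

#' Simulate a full acquisition session
#'
#' Forward model of the rig: per-channel signal dynamics -> sensor
#' response -> LED brightness -> rendered camera frames, with the
#' aligned ground truth for every stage. Produces exactly
#' `floor(duration_s / interval_s)` frames (720 at the default 60 min /
#' 5 s settings) and is byte-identical for identical configuration and
#' seed. The RNG stream is derived from `cfg$seed` and does not disturb
#' the caller's RNG.
#'
#' @param cfg A [session_config()].
#' @param sensors A [sensor_population()] with `n_channels(cfg)` sensors.
#' @param grid A [led_grid()] matching `cfg`'s grid and frame geometry.
#' @param dynamics A [signal_dynamics()]; ignored when `common_signal`
#'   is given.
#' @param common_signal Optional scalar (or per-frame vector) signal fed
#'   identically to every channel — the common-signal wiring used for
#'   gain calibration sessions.
#' @return List with `frames` (list of `ppc_frame`) and `truth`, a
#'   `ppc_ground_truth` holding `signals` (brightness fractions,
#'   channel x frame), `true_centers`, and `true_gains`.
#' @examples
#' cfg <- session_config(n_rows = 2, n_cols = 3, duration_s = 20,
#'                       interval_s = 5, image_width = 64,
#'                       image_height = 48)
#' rig <- led_grid(2, 3, 64, 48, jitter_sd = 0.5)
#' pop <- sensor_population(6, seed = 2)
#' ses <- simulate_session(cfg, pop, rig)
#' length(ses$frames)  # 4
#' @export
simulate_session <- function(cfg, sensors, grid,
                             dynamics = signal_dynamics(),
                             common_signal = NULL) {
  if (!inherits(cfg, "ppc_session_config"))
    ppc_stop("invalid_config", "'cfg' must be a session_config")
  nc <- n_channels(cfg)
  if (length(sensors$gains) != nc)
    ppc_stop("invalid_config", "sensor population has %d sensors, config needs %d",
             length(sensors$gains), nc)
  if (grid$n_rows != cfg$n_rows || grid$n_cols != cfg$n_cols)
    ppc_stop("invalid_config", "grid dimensions do not match session config")
  nf <- n_frames(cfg)
  with_local_seed(cfg$seed, {
    sig <- simulate_signals(cfg, dynamics, common_signal)
    bright <- matrix(0, nc, nf)
    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      bright[, f] <- sensor_response(sig[, f], sensors$gains,
                                     sensors$saturation_level)
      frames[[f]] <- render_frame(bright[, f], grid, cfg,
                                  noise_sd = sensors$noise_sd,
                                  index = f - 1L,
                                  timestamp = (f - 1L) * cfg$interval_s)
    }
    truth <- structure(list(signals = bright,
                            true_centers = grid$true_centers,
                            true_gains = sensors$gains),
                       class = "ppc_ground_truth")
    list(frames = frames, truth = truth)
  })
}

#' Render the all-LEDs-on calibration frame
#'
#' Noise-free frame with every LED at full brightness, used to detect
#' spot centres for the vector map.
#'
#' @param grid A [led_grid()].
#' @return A `ppc_frame`.
#' @export
calibration_frame <- function(grid) {
  render_frame(rep(1, grid$n_rows * grid$n_cols), grid)
}

#' Write / read frame sequences as image files
#'
#' Frames are written as `frame_00000.png`, ... (lossless PNG by
#' default). `format = "jpeg"` re-encodes through JPEG to emulate the
#' storage format of the original acquisition software, including its
#' compression artifacts (requires the \pkg{jpeg} package).
#'
#' @param frames List of `ppc_frame`.
#' @param dir Output directory (created if missing).
#' @param format `"png"` (default, lossless) or `"jpeg"`.
#' @param quality JPEG quality in `[0, 1]` (ignored for PNG).
#' @return `write_frames()`: the file paths, invisibly. `read_frames()`:
#'   a list of `ppc_frame` ordered by filename, timestamps
#'   `index * interval_s`.
#' @export
write_frames <- function(frames, dir, format = c("png", "jpeg"),
                         quality = 0.95) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "png") "png" else "jpg"
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    path <- file.path(dir, sprintf("frame_%05d.%s", fr$index, ext))
    img <- fr$pixels / 255
    if (format == "png") {
      png::writePNG(img, path)
    } else {
      if (!requireNamespace("jpeg", quietly = TRUE))
        ppc_stop("invalid_config", "JPEG output requires the 'jpeg' package")
      jpeg::writeJPEG(img, path, quality = quality)
    }
    paths[i] <- path
  }
  invisible(paths)
}

#' @rdname write_frames
#' @param interval_s Sampling interval used to reconstruct timestamps.
#' @export
read_frames <- function(dir, interval_s = 5) {
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.(png|jpg|jpeg)$",
                           full.names = TRUE))
  if (length(paths) == 0L)
    ppc_stop("sequence", "no frame_*.png/jpg files found in '%s'", dir)
  lapply(seq_along(paths), function(i) {
    p <- paths[i]
    img <- if (grepl("\\.png$", p)) png::readPNG(p)
    else {
      if (!requireNamespace("jpeg", quietly = TRUE))
        ppc_stop("invalid_config", "JPEG input requires the 'jpeg' package")
      jpeg::readJPEG(p)
    }
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    px <- round(img[, , 1:3] * 255)
    storage.mode(px) <- "integer"
    idx <- as.integer(sub("^frame_(\\d+)\\..*$", "\\1", basename(p)))
    structure(list(pixels = px, index = idx,
                   timestamp = idx * interval_s),
              class = "ppc_frame")
  })
}

#' Write ground truth to plain-text files
#'
#' Brightness signals go to a delimited table (`channel`, `frame`,
#' `brightness`); spot centres and gains to a JSON sidecar.
#'
#' @param truth A `ppc_ground_truth` from [simulate_session()].
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nf <- ncol(truth$signals); nc <- nrow(truth$signals)
  tab <- data.frame(
    channel = rep(seq_len(nc), times = max(nf, 0)),
    frame = rep(seq_len(nf) - 1L, each = nc),
    brightness = as.vector(truth$signals)
  )
  sig_path <- file.path(dir, "ground_truth_signals.csv")
  utils::write.csv(tab, sig_path, row.names = FALSE)
  meta_path <- file.path(dir, "ground_truth_rig.json")
  jsonlite::write_json(list(
    true_centers = unname(as.matrix(truth$true_centers)),
    true_gains = truth$true_gains
  ), meta_path, digits = NA)
  invisible(c(sig_path, meta_path))
}
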