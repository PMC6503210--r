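#' Acquisition session configuration
#'
#' Describes one acquisition session: grid dimensions of the LED matrix,
#' session duration and sampling interval, and the camera frame geometry.
#' The number of frames is `floor(duration_s / interval_s)`; at the default
#' 60 min / 5 s settings a session yields 720 frames.
#'
#' @param n_rows,n_cols LED matrix dimensions (default 10 x 20 = 200 channels).
#' @param duration_s Session duration in seconds (>= 0; default 3600).
#' @param interval_s Sampling interval in seconds (> 0; default 5).
#' @param image_width,image_height Camera frame size in pixels (default
#'   320 x 240).
#' @param seed Integer seed driving the session's noise and signal dynamics.
#' @return An object of class `ppc_session_config`.
#' @examples
#' cfg <- session_config()
#' n_frames(cfg)  # 720
#' @export
session_config <- function(n_rows = 10L, n_cols = 20L,
                           duration_s = 3600, interval_s = 5,
                           image_width = 320L, image_height = 240L,
                           seed = 1L) {
  stopifnot_scalar_number(n_rows, "n_rows", min = 1)
  stopifnot_scalar_number(n_cols, "n_cols", min = 1)
  stopifnot_scalar_number(duration_s, "duration_s", min = 0)
  stopifnot_scalar_number(interval_s, "interval_s", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(image_width, "image_width", min = 8)
  stopifnot_scalar_number(image_height, "image_height", min = 8)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    duration_s = duration_s, interval_s = interval_s,
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    seed = as.integer(seed)
  ), class = "ppc_session_config")
}

#' Number of channels and frames of a session configuration
#'
#' @param cfg A [session_config()].
#' @return `n_channels()`: `n_rows * n_cols`. `n_frames()`:
#'   `floor(duration_s / interval_s)`.
#' @export
n_channels <- function(cfg) cfg$n_rows * cfg$n_cols

#' @rdname n_channels
#' @export
n_frames <- function(cfg) as.integer(floor(cfg$duration_s / cfg$interval_s))

#' Sensor population with manufacturing gain spread
#'
#' Models the per-channel amplifier chain. Each sensor has a fixed
#' multiplicative gain drawn once per population (manufacturing
#' variation, constant within a session), a camera noise level expressed
#' as a fraction of full scale, and a saturation level: the signal (in
#' signal units) at which LED brightness reaches 1.0.
#'
#' @param n The number of sensors.
#' @param gain_sdlog Log-normal sd of the gain spread (default 0.1, i.e.
#'   roughly a 10% spread around unity).
#' @param noise_sd Additive pixel noise as a fraction of full scale
#'   (default 0.01).
#' @param saturation_level Signal units at which brightness saturates
#'   (default 1).
#' @param seed Seed for the one-off gain draw.
#' @param gains Optional explicit gain vector (overrides the draw).
#' @return An object of class `ppc_sensor_population`.
#' @export
sensor_population <- function(n, gain_sdlog = 0.1, noise_sd = 0.01,
                              saturation_level = 1, seed = 1L,
                              gains = NULL) {
  stopifnot_scalar_number(n, "n", min = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  if (saturation_level <= 0)
    ppc_stop("invalid_config", "'saturation_level' must be > 0 (got %g)",
             saturation_level)
  if (is.null(gains)) {
    gains <- with_local_seed(seed, stats::rlnorm(n, meanlog = 0, sdlog = gain_sdlog))
  }
  if (length(gains) != n || any(gains <= 0))
    ppc_stop("invalid_config", "gains must be %d positive values", n)
  structure(list(
    gains = gains, noise_sd = noise_sd,
    saturation_level = saturation_level, seed = as.integer(seed)
  ), class = "ppc_sensor_population")
}

#' LED grid geometry on the image plane
#'
#' Lays the LED matrix out on the camera image: nominal spot centres on a
#' regular lattice with margins, plus a fixed per-LED geometric jitter
#' drawn once at construction (the physical LEDs are soldered slightly
#' off their ideal positions and do not move between sessions). Each spot
#' is an isotropic Gaussian of sd `psf_sigma`, further blurred by the
#' semi-translucent diffuser sheet (`diffuser_sigma`); the two convolve
#' to a total spot sd of `sqrt(psf_sigma^2 + diffuser_sigma^2)`.
#'
#' @param n_rows,n_cols Grid dimensions (default 10 x 20).
#' @param image_width,image_height Frame size in pixels.
#' @param jitter_sd Geometric jitter sd in px (default 1; truncated at
#'   3 sd so spots stay well separated).
#' @param psf_sigma LED spot spread in px (default 1.5).
#' @param diffuser_sigma Extra blur from the diffuser sheet in px
#'   (default 1).
#' @param background_level Dark-background pixel intensity, 0-255
#'   (default 8).
#' @param seed Seed for the one-off jitter draw.
#' @return An object of class `ppc_led_grid` with `nominal_centers` and
#'   `true_centers`, each an n x 2 matrix of 0-based (x, y) coordinates
#'   in row-major LED order (top-left LED first).
#' @export
led_grid <- function(n_rows = 10L, n_cols = 20L,
                     image_width = 320L, image_height = 240L,
                     jitter_sd = 1, psf_sigma = 1.5, diffuser_sigma = 1,
                     background_level = 8, seed = 1L) {
  stopifnot_scalar_number(jitter_sd, "jitter_sd", min = 0)
  stopifnot_scalar_number(psf_sigma, "psf_sigma", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(diffuser_sigma, "diffuser_sigma", min = 0)
  if (background_level < 0 || background_level > 255)
    ppc_stop("invalid_config", "'background_level' must lie in [0, 255]")
  n <- n_rows * n_cols
  # lattice with a one-pitch margin on every side; 0-based coordinates
  xs <- (seq_len(n_cols)) * image_width / (n_cols + 1)
  ys <- (seq_len(n_rows)) * image_height / (n_rows + 1)
  nominal <- cbind(
    x = rep(xs, times = n_rows),
    y = rep(ys, each = n_cols)
  )
  jit <- with_local_seed(seed, {
    j <- matrix(stats::rnorm(2 * n, sd = jitter_sd), ncol = 2)
    pmin(pmax(j, -3 * jitter_sd), 3 * jitter_sd)
  })
  true_centers <- nominal + jit
  true_centers[, 1] <- pmin(pmax(true_centers[, 1], 0), image_width - 1)
  true_centers[, 2] <- pmin(pmax(true_centers[, 2], 0), image_height - 1)
  colnames(true_centers) <- c("x", "y")
  d <- min_pairwise_distance(true_centers)
  if (d <= 2 * psf_sigma)
    ppc_stop("invalid_config",
             "spot centres too close: min pairwise distance %.2f px <= 2*psf_sigma = %.2f px",
             d, 2 * psf_sigma)
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    nominal_centers = nominal, true_centers = true_centers,
    jitter_sd = jitter_sd, psf_sigma = psf_sigma,
    diffuser_sigma = diffuser_sigma,
    background_level = background_level, seed = as.integer(seed)
  ), class = "ppc_led_grid")
}

min_pairwise_distance <- function(centers) {
  if (nrow(centers) < 2) return(Inf)
  min(stats::dist(centers))
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
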