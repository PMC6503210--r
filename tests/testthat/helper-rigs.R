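# Small noise-free rigs used across the suite. Full-size (200-LED,
# 320x240) rigs are built only where a property is about that scale.

tiny_rig <- function(n_rows = 2L, n_cols = 3L, image_width = 64L,
                     image_height = 48L, duration_s = 20, interval_s = 5,
                     jitter_sd = 0, noise_sd = 0, seed = 1L,
                     gains = rep(1, n_rows * n_cols), ...) {
  cfg <- session_config(n_rows, n_cols, duration_s, interval_s,
                        image_width, image_height, seed = seed)
  grid <- led_grid(n_rows, n_cols, image_width, image_height,
                   jitter_sd = jitter_sd, background_level = 0,
                   seed = seed, ...)
  pop <- sensor_population(n_rows * n_cols, noise_sd = noise_sd,
                           seed = seed, gains = gains)
  list(cfg = cfg, grid = grid, pop = pop,
       layout = layout_spec(n_rows, n_cols))
}

full_rig <- function(seed = 1L, jitter_sd = 1, noise_sd = 0.005,
                     gain_sdlog = 0.1, duration_s = 100, interval_s = 5) {
  cfg <- session_config(10L, 20L, duration_s, interval_s, 320L, 240L,
                        seed = seed)
  grid <- led_grid(10L, 20L, 320L, 240L, jitter_sd = jitter_sd,
                   seed = seed)
  pop <- sensor_population(200L, gain_sdlog = gain_sdlog,
                           noise_sd = noise_sd, seed = seed + 1L)
  list(cfg = cfg, grid = grid, pop = pop, layout = layout_spec())
}

# decoded grayscale of a frame, for argmax oracles
frame_gray <- function(frame) {
  (frame$pixels[, , 1] + frame$pixels[, , 2] + frame$pixels[, , 3]) / 3
}

random_sample_matrix <- function(n_rows = 10, n_cols = 20) {
  sample_matrix(matrix(runif(n_rows * n_cols, 0, 100), n_rows, n_cols))
}
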