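test_that("frame count is floor(duration / interval) across settings", {
  cases <- list(
    c(3600, 5, 720),   # one-hour session at 5 s
    c(0, 5, 0),        # degenerate duration
    c(17, 5, 3),
    c(7200, 60, 120),
    c(180, 3, 60)
  )
  for (cs in cases) {
    cfg <- session_config(2, 3, duration_s = cs[1], interval_s = cs[2],
                          image_width = 64, image_height = 48)
    expect_identical(n_frames(cfg), as.integer(cs[3]))
  }
  rig <- tiny_rig(duration_s = 3600, interval_s = 5)
  ses <- simulate_session(rig$cfg, rig$pop, rig$grid, common_signal = 0.4)
  expect_length(ses$frames, 720L)
  expect_identical(dim(ses$truth$signals), c(6L, 720L))
})

test_that("zero-duration session yields no frames and empty ground truth", {
  rig <- tiny_rig(duration_s = 0)
  ses <- simulate_session(rig$cfg, rig$pop, rig$grid)
  expect_length(ses$frames, 0L)
  expect_identical(ncol(ses$truth$signals), 0L)
})

test_that("invalid session configuration is rejected", {
  expect_error(session_config(interval_s = 0), class = "ppc_invalid_config_error")
  expect_error(session_config(interval_s = -5), class = "ppc_invalid_config_error")
  expect_error(session_config(duration_s = -1), class = "ppc_invalid_config_error")
  expect_error(sensor_population(4, saturation_level = -1),
               class = "ppc_invalid_config_error")
})

test_that("identical config and seed reproduce byte-identical sessions", {
  rig <- tiny_rig(noise_sd = 0.01, jitter_sd = 0.5, seed = 11)
  a <- simulate_session(rig$cfg, rig$pop, rig$grid)
  b <- simulate_session(rig$cfg, rig$pop, rig$grid)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  # a different session seed changes the pixels but not the rig geometry
  cfg2 <- rig$cfg; cfg2$seed <- 99L
  c2 <- simulate_session(cfg2, rig$pop, rig$grid)
  expect_false(identical(a$frames, c2$frames))
  expect_identical(a$truth$true_centers, c2$truth$true_centers)
})

test_that("sensor response is clamped, saturating and monotone", {
  expect_identical(sensor_response(0, 1, 1), 0)
  expect_identical(sensor_response(1, 1, 1), 1)
  expect_identical(sensor_response(5, 0.3, 2), 1)  # at/above saturation
  expect_error(sensor_response(1, 1, -2), class = "ppc_invalid_config_error")
  expect_error(sensor_response(1, 0, 1), class = "ppc_invalid_config_error")
  # brute-force monotonicity scan over a grid of inputs and gains
  s <- seq(-0.2, 1.5, length.out = 300)
  for (gain in c(0.5, 1, 1.7)) {
    b <- sensor_response(s, gain, 1)
    expect_true(all(diff(b) >= 0))
    expect_true(all(b >= 0 & b <= 1))
  }
})

test_that("dark frames sit exactly at the background level without noise", {
  rig <- tiny_rig()
  grid8 <- led_grid(2, 3, 64, 48, jitter_sd = 0, background_level = 8)
  fr <- render_frame(rep(0, 6), grid8)
  expect_true(all(fr$pixels == 8L))
})

test_that("a single lit channel puts the global argmax at its centre", {
  rig <- tiny_rig(jitter_sd = 0.8, seed = 7)
  for (k in c(1L, 4L, 6L)) {
    b <- rep(0, 6); b[k] <- 1
    fr <- render_frame(b, rig$grid)
    g <- frame_gray(fr)
    am <- which(g == max(g), arr.ind = TRUE)[1, ]
    x <- am[2] - 1; y <- am[1] - 1   # 0-based
    ctr <- rig$grid$true_centers[k, ]
    expect_lt(sqrt((x - ctr[1])^2 + (y - ctr[2])^2), 1 + 1e-9)
  }
})

test_that("diffuser blur bleeds light into the gap between adjacent spots", {
  grid <- led_grid(1, 2, 40, 24, jitter_sd = 0, psf_sigma = 1.5,
                   diffuser_sigma = 4, background_level = 8)
  fr <- render_frame(c(1, 1), grid)
  ctr <- grid$true_centers
  mid <- round(colMeans(ctr))
  midpix <- fr$pixels[mid[2] + 1L, mid[1] + 1L, 1]
  expect_gt(midpix, grid$background_level)
})

test_that("centre-window intensity is monotone in channel brightness", {
  rig <- tiny_rig()
  levels <- seq(0, 1, length.out = 12)
  k <- 2L
  ctr <- round(rig$grid$true_centers[k, ])
  means <- vapply(levels, function(b) {
    v <- rep(0, 6); v[k] <- b
    g <- frame_gray(render_frame(v, rig$grid))
    mean(g[ctr[2] + (0:2), ctr[1] + (0:2)])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_gt(means[12], means[1])
})

test_that("renderer rejects mismatched input lengths and out-of-bounds centres", {
  rig <- tiny_rig()
  expect_error(render_frame(rep(1, 5), rig$grid), class = "ppc_render_error")
  bad <- rig$grid
  bad$true_centers[1, 1] <- 120   # beyond the 64-px width
  expect_error(render_frame(rep(1, 6), bad), class = "ppc_render_error")
})

test_that("frame files round-trip losslessly through PNG", {
  rig <- tiny_rig(noise_sd = 0.01, seed = 5)
  ses <- simulate_session(rig$cfg, rig$pop, rig$grid)
  d <- withr::local_tempdir()
  write_frames(ses$frames, d)
  back <- read_frames(d, interval_s = rig$cfg$interval_s)
  expect_identical(lapply(back, `[[`, "pixels"),
                   lapply(ses$frames, `[[`, "pixels"))
  expect_identical(vapply(back, `[[`, numeric(1), "timestamp"),
                   vapply(ses$frames, `[[`, numeric(1), "timestamp"))
})

test_that("step dynamics perturb the signal at the dosing times", {
  cfg <- session_config(2, 3, duration_s = 2400, interval_s = 60,
                        image_width = 64, image_height = 48, seed = 3)
  pop <- sensor_population(6, noise_sd = 0, seed = 3)
  grid <- led_grid(2, 3, 64, 48, jitter_sd = 0, seed = 3)
  dyn <- signal_dynamics(drift_sd = 0, step_times_s = c(900, 1800),
                         step_amplitude = 0.1)
  ses <- simulate_session(cfg, pop, grid, dynamics = dyn)
  sig <- ses$truth$signals
  ts <- (seq_len(ncol(sig)) - 1) * 60
  pre <- sig[1, ts < 900]
  mid <- sig[1, ts >= 900 & ts < 1800]
  post <- sig[1, ts >= 1800]
  expect_true(all(abs(diff(pre)) < 1e-12))
  expect_gt(mean(mid), mean(pre))
  expect_gt(mean(post), mean(mid))
})
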