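make_series <- function(mats, interval_s = 5) {
  signal_series(lapply(seq_along(mats), function(i)
    sample_matrix(mats[[i]], timestamp = (i - 1) * interval_s,
                  role = "calibrated")), interval_s)
}

test_that("the averaging window reduces 20 matrices to 4000 measurements / 100 s", {
  mats <- replicate(25, matrix(runif(200, 0, 100), 10, 20), simplify = FALSE)
  h <- average_encoded_matrix(make_series(mats), window = 20)
  expect_identical(h$n_frames_averaged, 20L)
  expect_identical(h$n_measurements, 4000L)
  expect_equal(h$window_seconds, 100)
  expect_equal(h$values, Reduce(`+`, mats[1:20]) / 20 / 100)
})

test_that("a constant series averages to any one matrix over 100", {
  m <- matrix(runif(200, 0, 100), 10, 20)
  h <- average_encoded_matrix(make_series(replicate(20, m, simplify = FALSE)),
                              window = 20)
  expect_equal(h$values, m / 100)
})

test_that("tiny grids average exactly", {
  s <- make_series(list(matrix(20, 1, 1), matrix(40, 1, 1)))
  h <- average_encoded_matrix(s, window = 2)
  expect_equal(h$values, matrix(0.30, 1, 1))
})

test_that("windows larger than the series are rejected; offsets honoured", {
  mats <- lapply(1:5, function(i) matrix(i * 10, 1, 1))
  s <- make_series(mats)
  expect_error(average_encoded_matrix(s, window = 6),
               class = "ppc_window_error")
  expect_error(average_encoded_matrix(s, window = 4, offset = 2),
               class = "ppc_window_error")
  h <- average_encoded_matrix(s, window = 2, offset = 3)
  expect_equal(h$values, matrix(0.45, 1, 1))  # mean of 40 and 50, over 100
})

test_that("colormap endpoints encode to the anchor colours and round-trip", {
  spec <- colormap_spec()
  h0 <- heatmap_matrix(matrix(0, 10, 20))
  h1 <- heatmap_matrix(matrix(1, 10, 20))
  img0 <- encode_colormap(h0, spec)
  img1 <- encode_colormap(h1, spec)
  expect_equal(as.vector(img0[1, 1, ]), spec$low)
  expect_equal(as.vector(img1[1, 1, ]), spec$high)
  expect_true(all(decode_colormap(img0, spec)$values == 0))
  expect_true(all(decode_colormap(img1, spec)$values == 1))
  hmid <- heatmap_matrix(matrix(0.5, 10, 20))
  expect_equal(as.vector(encode_colormap(hmid, spec)[1, 1, ]), spec$mid)
})

test_that("colormap round-trip error is bounded by 8-bit quantisation", {
  spec <- colormap_spec()
  set.seed(33)
  worst <- 0
  for (i in 1:5) {  # 5 x 200 = 1000 random cells
    h <- heatmap_matrix(matrix(runif(200), 10, 20))
    back <- decode_colormap(encode_colormap(h, spec), spec)
    worst <- max(worst, max(abs(back$values - h$values)))
  }
  expect_lte(worst, 1 / 255)
})

test_that("decode rejects off-grid dimensions and off-curve colours", {
  spec <- colormap_spec()
  expect_error(decode_colormap(array(0.5, c(101, 240, 3)), spec),
               class = "ppc_format_error")
  green <- array(0, c(10, 20, 3)); green[, , 2] <- 1
  expect_error(decode_colormap(green, spec, 10, 20),
               class = "ppc_decode_error")
})

test_that("non-invertible anchor sets are rejected at construction", {
  # half-intensity anchors collapse to the same grays near the midpoint
  expect_error(colormap_spec(low = c(0, 0, 0.5), high = c(0.5, 0, 0)),
               class = "ppc_invalid_config_error")
})

test_that("heatmaps survive the PNG colormap files", {
  spec <- colormap_spec()
  h <- heatmap_matrix(matrix(runif(200), 10, 20))
  d <- withr::local_tempdir()
  p <- file.path(d, "h.png")
  save_heatmap(h, p, spec)
  img <- png::readPNG(p)
  back <- decode_colormap(img, spec)
  expect_lte(max(abs(back$values - h$values)), 1 / 255)
})

test_that("the default synthetic cohort reproduces the study arm sizes", {
  cohort <- synthetic_cohort(seed = 5)
  expect_length(cohort, 36L)
  labs <- vapply(cohort, `[[`, character(1), "label")
  grps <- vapply(cohort, `[[`, character(1), "group")
  expect_identical(sum(labs == "healthy" & grps == "female"), 5L)
  expect_identical(sum(labs == "diabetes" & grps == "female"), 8L)
  expect_identical(sum(labs == "healthy" & grps == "male"), 13L)
  expect_identical(sum(labs == "diabetes" & grps == "male"), 10L)
})

test_that("training is deterministic under a fixed seed", {
  cohort <- synthetic_cohort(seed = 5)
  probe <- synthetic_cohort(sizes = c(healthy_male = 3, diabetic_male = 3),
                            seed = 77)
  m1 <- train_classifier(cohort, seed = 9, hidden = 8)
  m2 <- train_classifier(cohort, seed = 9, hidden = 8)
  s1 <- vapply(probe, function(h) predict_heatmap(m1, h), numeric(1))
  s2 <- vapply(probe, function(h) predict_heatmap(m2, h), numeric(1))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("separable synthetic classes are classified with high held-out accuracy", {
  train <- synthetic_cohort(sizes = c(healthy_female = 50, diabetic_female = 50,
                                      healthy_male = 50, diabetic_male = 50),
                            separation = 0.2, seed = 1)
  test <- synthetic_cohort(sizes = c(healthy_female = 15, diabetic_female = 15,
                                     healthy_male = 15, diabetic_male = 15),
                           separation = 0.2, seed = 2)
  model <- train_classifier(train, seed = 3)
  pred <- vapply(test, function(h)
    classify_score(predict_heatmap(model, h)), character(1))
  truth <- ifelse(vapply(test, `[[`, character(1), "label") == "diabetes",
                  "predisposed", "healthy")
  expect_gte(mean(pred == truth), 0.9)
})

test_that("an information-free cohort scores near chance", {
  train <- synthetic_cohort(sizes = c(healthy_female = 40, diabetic_female = 40,
                                      healthy_male = 40, diabetic_male = 40),
                            separation = 0, seed = 11)
  test <- synthetic_cohort(sizes = c(healthy_female = 20, diabetic_female = 20,
                                     healthy_male = 20, diabetic_male = 20),
                           separation = 0, seed = 12)
  model <- train_classifier(train, seed = 13)
  pred <- vapply(test, function(h)
    classify_score(predict_heatmap(model, h)), character(1))
  truth <- ifelse(vapply(test, `[[`, character(1), "label") == "diabetes",
                  "predisposed", "healthy")
  acc <- mean(pred == truth)
  expect_gte(acc, 0.5 - 3 * sqrt(0.25 / 80))   # within binomial noise of 0.5
  expect_lte(acc, 0.5 + 3 * sqrt(0.25 / 80))
})

test_that("training regimes filter by cohort group", {
  cohort <- synthetic_cohort(seed = 5)
  mf <- train_classifier(cohort, seed = 1, regime = "female", hidden = 4)
  mm <- train_classifier(cohort, seed = 1, regime = "male", hidden = 4)
  expect_identical(mf$n_train, 13L)   # 5 healthy + 8 diabetic female
  expect_identical(mm$n_train, 23L)   # 13 + 10 male
})

test_that("degenerate classifier inputs raise the documented errors", {
  one_class <- synthetic_cohort(sizes = c(healthy_male = 6, diabetic_male = 1),
                                seed = 4)[1:6]
  expect_error(train_classifier(one_class, seed = 1),
               class = "ppc_training_error")
  cohort <- synthetic_cohort(sizes = c(healthy_male = 4, diabetic_male = 4),
                             seed = 4)
  model <- train_classifier(cohort, seed = 1, hidden = 2)
  small <- heatmap_matrix(matrix(0.5, 5, 5))
  expect_error(predict_heatmap(model, small), class = "ppc_input_error")
})

test_that("the 50% threshold splits classes with an indeterminate boundary", {
  expect_identical(classify_score(0.49), "healthy")
  expect_identical(classify_score(0.51), "predisposed")
  expect_identical(classify_score(0.5), "indeterminate")
})

test_that("cohorts round-trip through a directory of heatmap CSVs", {
  cohort <- synthetic_cohort(sizes = c(healthy_female = 2, diabetic_male = 2),
                             seed = 3)
  d <- withr::local_tempdir()
  save_cohort(cohort, d)
  back <- load_cohort(d)
  expect_length(back, 4L)
  expect_setequal(vapply(back, `[[`, character(1), "label"),
                  c("healthy", "diabetes"))
  orig_ids <- sort(vapply(cohort, `[[`, character(1), "subject_id"))
  expect_identical(sort(vapply(back, `[[`, character(1), "subject_id")),
                   orig_ids)
})
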