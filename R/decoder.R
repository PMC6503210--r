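#' Convert an RGB pixel to a percentage intensity
#'
#' Maps an 8-bit RGB triple to the percentage scale on which all sample
#' matrices live: pure black = 0%, pure white = 100%, linear in between
#' (no gamma). The 24-bit value is reduced to one scalar by the
#' arithmetic mean of the three channels (the LEDs are white, so the
#' channels are nominally equal); `mode` offers max-channel and ITU
#' BT.601 luma alternatives.
#'
#' @param rgb Numeric triple (or n x 3 matrix) of channel values in
#'   `[0, 255]`.
#' @param mode Grayscale reduction: `"mean"` (default), `"max"`, or
#'   `"luma"`.
#' @return Percentage(s) in `[0, 100]`.
#' @examples
#' pixel_to_percent(c(255, 255, 255))  # 100
#' pixel_to_percent(c(0, 0, 0))        # 0
#' @export
pixel_to_percent <- function(rgb, mode = c("mean", "max", "luma")) {
  mode <- match.arg(mode)
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3, byrow = TRUE)
  if (ncol(m) != 3) ppc_stop("domain", "rgb must have three channels")
  if (any(!is.finite(m)) || any(m < 0) || any(m > 255))
    ppc_stop("domain", "rgb channel values must lie in [0, 255]")
  gray <- switch(mode,
    mean = rowMeans(m),
    max = apply(m, 1, max),
    luma = as.vector(m %*% c(0.299, 0.587, 0.114))
  )
  out <- 100 * gray / 255
  if (!is.matrix(rgb) && length(rgb) == 3) out[[1]] else out
}

#' A single decoded sample matrix
#'
#' Internal constructor for the `n_rows x n_cols` grid of percentage
#' intensities decoded from one frame.
#'
#' @param values Numeric matrix of percentages in `[0, 100]`.
#' @param timestamp Seconds from session start.
#' @param role One of `"test"`, `"real"`, `"calibrated"`.
#' @return A `ppc_sample_matrix`.
#' @export
sample_matrix <- function(values, timestamp = 0, role = "real") {
  if (!is.matrix(values) || length(values) == 0L)
    ppc_stop("domain", "'values' must be a non-empty matrix")
  if (any(values < 0 | values > 100))
    ppc_stop("domain", "sample values must lie in [0, 100]")
  if (!role %in% c("test", "real", "calibrated"))
    ppc_stop("domain", "role must be 'test', 'real' or 'calibrated'")
  structure(list(values = values, timestamp = timestamp, role = role),
            class = "ppc_sample_matrix")
}

#' Decode one frame into a sample matrix
#'
#' Samples exactly one pixel per LED — the pixel at the LED's vector-map
#' coordinate — and converts it to a percentage. Cell `[row, col]` of the
#' result holds the LED with row-major index `(row-1)*n_cols + col`. An
#' optional robust mode averages a 3x3 window instead of the single
#' centre pixel (off by default; the single-pixel read is the reference
#' behaviour).
#'
#' @param frame A `ppc_frame`.
#' @param map A `ppc_vector_map` matching the frame dimensions.
#' @param layout A [layout_spec()] giving the grid shape.
#' @param role Role tag of the resulting matrix (default `"real"`).
#' @param robust Use a 3x3-mean window instead of one pixel.
#' @param mode Grayscale reduction passed to [pixel_to_percent()].
#' @return A `ppc_sample_matrix`.
#' @export
extract_matrix <- function(frame, map, layout, role = "real",
                           robust = FALSE, mode = "mean") {
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (attr(map, "image_width") != w || attr(map, "image_height") != h)
    ppc_stop("map_frame_mismatch",
             "vector map is for %dx%d but the frame is %dx%d",
             attr(map, "image_width"), attr(map, "image_height"), w, h)
  n <- layout$n_rows * layout$n_cols
  if (nrow(map) != n)
    ppc_stop("map_frame_mismatch", "map has %d entries, layout needs %d",
             nrow(map), n)
  vals <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  for (k in seq_len(n)) {
    xi <- map$x[k]; yi <- map$y[k]
    if (xi < 0 || xi >= w || yi < 0 || yi >= h)
      ppc_stop("map_frame_mismatch",
               "map coordinate (%d, %d) lies outside the frame", xi, yi)
    rgb <- if (robust) {
      r0 <- max(1, yi); r1 <- min(h, yi + 2)  # 3x3 around (yi+1, xi+1)
      c0 <- max(1, xi); c1 <- min(w, xi + 2)
      c(mean(px[r0:r1, c0:c1, 1]), mean(px[r0:r1, c0:c1, 2]),
        mean(px[r0:r1, c0:c1, 3]))
    } else {
      px[yi + 1L, xi + 1L, ]
    }
    i <- map$led_index[k]
    row <- (i - 1L) %/% layout$n_cols + 1L
    col <- (i - 1L) %% layout$n_cols + 1L
    vals[row, col] <- pixel_to_percent(as.numeric(rgb), mode = mode)
  }
  sample_matrix(vals, timestamp = frame$timestamp, role = role)
}

#' Decode a frame sequence into a signal series
#'
#' Applies [extract_matrix()] to every frame, preserving order, and
#' collects the matrices with their common sampling interval.
#'
#' @inheritParams extract_matrix
#' @param frames Non-empty list of `ppc_frame` of identical dimensions.
#' @param interval_s Sampling interval in seconds (default: inferred
#'   from the first two timestamps, else 5).
#' @return A `ppc_signal_series`: list with `matrices` and `interval_s`.
#' @export
decode_sequence <- function(frames, map, layout, role = "real",
                            robust = FALSE, mode = "mean",
                            interval_s = NULL) {
  if (length(frames) == 0L)
    ppc_stop("sequence", "cannot decode an empty frame sequence")
  dims <- vapply(frames, function(f) dim(f$pixels)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    ppc_stop("sequence", "frames have inconsistent dimensions")
  mats <- lapply(frames, extract_matrix, map = map, layout = layout,
                 role = role, robust = robust, mode = mode)
  if (is.null(interval_s)) {
    interval_s <- if (length(frames) >= 2)
      frames[[2]]$timestamp - frames[[1]]$timestamp else 5
  }
  signal_series(mats, interval_s)
}

#' @rdname decode_sequence
#' @param matrices Time-ordered list of `ppc_sample_matrix`.
#' @export
signal_series <- function(matrices, interval_s) {
  if (length(matrices) == 0L)
    ppc_stop("sequence", "a signal series needs at least one matrix")
  shp <- dim(matrices[[1]]$values)
  ok <- vapply(matrices, function(m) identical(dim(m$values), shp), logical(1))
  if (!all(ok)) ppc_stop("sequence", "matrices in a series must share one shape")
  structure(list(matrices = matrices, interval_s = interval_s),
            class = "ppc_signal_series")
}

#' Total sample count of an acquisition campaign
#'
#' `Ns = n x f`: the number of scalar measurements taken by `n` channels
#' over `f` frames. One 200-channel subject at 720 frames yields
#' 144,000 samples; a 36-subject campaign (25,920 images) yields
#' 5,184,000.
#'
#' @param n_channels,n_frames Non-negative integers.
#' @return The product, as a double.
#' @examples
#' count_samples(200, 720)    # 144000
#' count_samples(200, 25920)  # 5184000
#' @export
count_samples <- function(n_channels, n_frames) {
  stopifnot_scalar_number(n_channels, "n_channels", min = 0)
  stopifnot_scalar_number(n_frames, "n_frames", min = 0)
  as.numeric(n_channels) * as.numeric(n_frames)
}

#' Write / read a decoded signal series
#'
#' Long delimited format: one row per `(frame_index, label, percent)`,
#' using the layout's sensor labels.
#'
#' @param series A `ppc_signal_series`.
#' @param path CSV path.
#' @param layout A [layout_spec()].
#' @return `read_series()` returns a `ppc_signal_series`.
#' @export
write_series <- function(series, path, layout) {
  n <- layout$n_rows * layout$n_cols
  idx <- seq_len(n)
  labs <- index_to_label(layout, idx)
  rows <- lapply(seq_along(series$matrices), function(f) {
    v <- t(series$matrices[[f]]$values)  # row-major flatten
    data.frame(frame_index = f - 1L, label = labs, percent = as.vector(v),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @param interval_s Sampling interval of the stored series.
#' @param role Role tag for the reconstructed matrices.
#' @export
read_series <- function(path, layout, interval_s = 5, role = "real") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  need <- c("frame_index", "label", "percent")
  if (!all(need %in% names(df)))
    ppc_stop("format", "series file lacks columns: %s",
             paste(setdiff(need, names(df)), collapse = ", "))
  frames <- sort(unique(df$frame_index))
  mats <- lapply(frames, function(f) {
    sub <- df[df$frame_index == f, ]
    i <- label_to_index(layout, sub$label)
    v <- matrix(NA_real_, layout$n_rows, layout$n_cols)
    v[cbind((i - 1L) %/% layout$n_cols + 1L, (i - 1L) %% layout$n_cols + 1L)] <-
      sub$percent
    if (anyNA(v)) ppc_stop("format", "frame %d is missing cells", f)
    sample_matrix(v, timestamp = f * interval_s, role = role)
  })
  signal_series(mats, interval_s)
}
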