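#' Average encoded matrix (heatmap) of a subject
#'
#' Reduces a decoded (preferably calibrated) series to one matrix: the
#' element-wise mean of `window` consecutive matrices, rescaled from
#' percent to `[0, 1]`. At the default window of 20 matrices a
#' 200-channel rig averages 4000 scalar measurements, the equivalent of
#' 100 s of signal at the 5-s sampling interval.
#'
#' @param series A `ppc_signal_series` with at least `offset + window`
#'   matrices.
#' @param window Number of matrices to average (default 20).
#' @param offset Number of leading matrices to skip (default 0).
#' @param subject_id,label,group Optional subject metadata; `label` is
#'   `"healthy"` or `"diabetes"`, `group` free-form (e.g. `"female"`).
#' @return A `ppc_heatmap`: list with `values` in `[0, 1]`,
#'   `n_frames_averaged`, `n_measurements`, `window_seconds`,
#'   `subject_id`, `label`, `group`.
#' @export
average_encoded_matrix <- function(series, window = 20L, offset = 0L,
                                   subject_id = NA_character_,
                                   label = NULL, group = NULL) {
  if (!inherits(series, "ppc_signal_series"))
    ppc_stop("domain", "'series' must be a ppc_signal_series")
  if (window < 1) ppc_stop("window", "window must be >= 1")
  nmat <- length(series$matrices)
  if (offset + window > nmat)
    ppc_stop("window",
             "window %d (offset %d) exceeds the series length %d",
             window, offset, nmat)
  sel <- series$matrices[(offset + 1L):(offset + window)]
  vals <- Reduce(`+`, lapply(sel, function(m) m$values)) / window / 100
  vals <- pmin(pmax(vals, 0), 1)
  heatmap_matrix(vals, n_frames_averaged = as.integer(window),
                 interval_s = series$interval_s,
                 subject_id = subject_id, label = label, group = group)
}

#' @rdname average_encoded_matrix
#' @param values Matrix of values in `[0, 1]`.
#' @param n_frames_averaged Number of frames behind the average.
#' @param interval_s Sampling interval used for the window-seconds
#'   bookkeeping.
#' @export
heatmap_matrix <- function(values, n_frames_averaged = 1L, interval_s = 5,
                           subject_id = NA_character_, label = NULL,
                           group = NULL) {
  if (!is.matrix(values) || any(values < 0 | values > 1))
    ppc_stop("domain", "heatmap values must be a matrix in [0, 1]")
  if (n_frames_averaged < 1)
    ppc_stop("domain", "n_frames_averaged must be >= 1")
  if (!is.null(label) && !label %in% c("healthy", "diabetes"))
    ppc_stop("domain", "label must be 'healthy' or 'diabetes'")
  structure(list(values = values,
                 n_frames_averaged = as.integer(n_frames_averaged),
                 n_measurements = as.integer(n_frames_averaged * length(values)),
                 window_seconds = n_frames_averaged * interval_s,
                 subject_id = subject_id, label = label, group = group),
            class = "ppc_heatmap")
}

#' Three-colour scale specification
#'
#' Piecewise-linear colormap through three anchors at positions 0, 0.5
#' and 1. The default runs blue (0) through white (0.5) to red (1),
#' matching the convention that red is 100% and blue 0%. The curve must
#' be invertible after 8-bit quantisation: construction verifies that
#' decoding the quantised colour of a dense ladder of values recovers
#' each value to within 1/255. (Darker anchors such as half-intensity
#' blue/red fail this: near the white midpoint both half-curves
#' quantise to the same grays.)
#'
#' @param low,mid,high RGB triples in `[0, 1]`.
#' @param n_lut Resolution of the lookup table used for inversion.
#' @return A `ppc_colormap_spec`.
#' @export
colormap_spec <- function(low = c(0, 0, 1), mid = c(1, 1, 1),
                          high = c(1, 0, 0), n_lut = 2048L) {
  for (a in list(low, mid, high))
    if (length(a) != 3 || any(a < 0 | a > 1))
      ppc_stop("invalid_config", "colormap anchors must be RGB triples in [0, 1]")
  spec <- structure(list(low = low, mid = mid, high = high,
                         n_lut = as.integer(n_lut)),
                    class = "ppc_colormap_spec")
  ladder <- seq(0, 1, length.out = 2049)
  back <- colormap_invert(round(colormap_color(spec, ladder) * 255) / 255, spec)
  if (max(abs(back$value - ladder)) > 1 / 255)
    ppc_stop("invalid_config",
             "colormap anchors are not invertible to within 8-bit precision")
  spec
}

# value(s) in [0,1] -> n x 3 RGB in [0,1] along the piecewise-linear curve
colormap_color <- function(spec, v) {
  v <- pmin(pmax(v, 0), 1)
  lo <- matrix(spec$low, length(v), 3, byrow = TRUE)
  mi <- matrix(spec$mid, length(v), 3, byrow = TRUE)
  hi <- matrix(spec$high, length(v), 3, byrow = TRUE)
  t1 <- pmin(v / 0.5, 1)
  t2 <- pmax((v - 0.5) / 0.5, 0)
  first <- lo * (1 - t1) + mi * t1
  second <- mi * (1 - t2) + hi * t2
  ifelse(matrix(v <= 0.5, length(v), 3), first, second)
}

# rgb (n x 3 in [0,1]) -> nearest curve point; returns value and distance
colormap_invert <- function(rgb, spec) {
  ts <- seq(0, 1, length.out = spec$n_lut)
  lut <- colormap_color(spec, ts)
  # squared distance of each pixel to each LUT colour
  d2 <- outer(rowSums(rgb^2), rowSums(lut^2), `+`) - 2 * rgb %*% t(lut)
  j <- max.col(-d2, ties.method = "first")
  list(value = ts[j], dist = sqrt(pmax(rowSums((rgb - lut[j, , drop = FALSE])^2), 0)))
}

#' Encode / decode a heatmap through the three-colour scale
#'
#' `encode_colormap()` renders the heatmap as an image of
#' `n_rows x n_cols` coloured rectangles (each `cell_px` pixels square),
#' quantised to 8 bits per channel. `decode_colormap()` reverses the
#' conversion: each cell's colour is projected back onto the colormap
#' curve, recovering the value to within 1/255 (the 8-bit quantisation
#' bound). Colours further than `tol` off the curve raise a decode
#' error; image dimensions that are not multiples of the grid raise a
#' format error.
#'
#' @param h A `ppc_heatmap`.
#' @param spec A [colormap_spec()].
#' @param cell_px Rectangle edge length in pixels (default 12).
#' @return `encode_colormap()`: an H x W x 3 array in `[0, 1]`.
#'   `decode_colormap()`: a `ppc_heatmap`.
#' @export
encode_colormap <- function(h, spec = colormap_spec(), cell_px = 12L) {
  v <- h$values
  cols <- round(colormap_color(spec, as.vector(v)) * 255) / 255
  nr <- nrow(v); nc <- ncol(v)
  img <- array(0, dim = c(nr * cell_px, nc * cell_px, 3))
  for (ch in 1:3) {
    cm <- matrix(cols[, ch], nr, nc)
    img[, , ch] <- cm[rep(seq_len(nr), each = cell_px),
                      rep(seq_len(nc), each = cell_px)]
  }
  img
}

#' @rdname encode_colormap
#' @param img An H x W x 3 array in `[0, 1]` produced by
#'   `encode_colormap()` (or read from PNG).
#' @param n_rows,n_cols Grid dimensions encoded in the image.
#' @param tol Maximum tolerated RGB distance off the colormap curve.
#' @export
decode_colormap <- function(img, spec = colormap_spec(), n_rows = 10L,
                            n_cols = 20L, tol = 0.02) {
  d <- dim(img)
  if (length(d) != 3 || d[3] < 3)
    ppc_stop("format", "expected an H x W x 3 image array")
  if (d[1] %% n_rows != 0 || d[2] %% n_cols != 0)
    ppc_stop("format",
             "image %dx%d is not a multiple of the %dx%d grid",
             d[2], d[1], n_cols, n_rows)
  cy <- d[1] %/% n_rows; cx <- d[2] %/% n_cols
  rows <- (seq_len(n_rows) - 1L) * cy + (cy + 1L) %/% 2L
  cols <- (seq_len(n_cols) - 1L) * cx + (cx + 1L) %/% 2L
  rgb <- cbind(as.vector(img[rows, cols, 1]),
               as.vector(img[rows, cols, 2]),
               as.vector(img[rows, cols, 3]))
  inv <- colormap_invert(rgb, spec)
  if (any(inv$dist > tol))
    ppc_stop("decode",
             "%d cell colour(s) lie off the colormap curve (max distance %.4f > %.4f)",
             sum(inv$dist > tol), max(inv$dist), tol)
  heatmap_matrix(matrix(inv$value, n_rows, n_cols))
}

#' Save / load heatmaps
#'
#' CSV grid of the `[0, 1]` values, or a colormapped PNG via
#' [encode_colormap()].
#'
#' @param h A `ppc_heatmap`.
#' @param path `.csv` or `.png` path.
#' @param spec Colormap used for PNG output.
#' @return `load_heatmap()` returns a `ppc_heatmap` (CSV only; use
#'   [decode_colormap()] for PNGs).
#' @export
save_heatmap <- function(h, path, spec = colormap_spec()) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(encode_colormap(h, spec), path)
  } else {
    utils::write.table(h$values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_heatmap
#' @export
load_heatmap <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  heatmap_matrix(m)
}
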