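#' Construct a vector map of LED pixel coordinates
#'
#' The vector map is the ordered list `v(n) = [x, y]` of per-LED pixel
#' coordinates in the camera image: one integer pixel per LED, used to
#' sample the LED's brightness from every frame. Indices must be the
#' complete set `1..n`; coordinates are 0-based (x = column, y = row)
#' and must lie inside the image.
#'
#' @param led_index Integer LED indices (must be a permutation of
#'   `1..n`); entries are stored sorted by index.
#' @param x,y Integer pixel coordinates, 0-based.
#' @param image_width,image_height Image dimensions in px.
#' @param label Optional character labels (see [assign_labels()]).
#' @param min_separation Separation floor in px; a map whose closest
#'   pair of entries is nearer than this is rejected (default 0 = no
#'   check).
#' @return An object of class `ppc_vector_map`: a data frame with
#'   columns `led_index`, `label`, `x`, `y` and attributes
#'   `image_width`, `image_height`.
#' @export
vector_map <- function(led_index, x, y, image_width, image_height,
                       label = NA_character_, min_separation = 0) {
  n <- length(led_index)
  if (n == 0L) ppc_stop("format", "a vector map needs at least one entry")
  if (length(x) != n || length(y) != n)
    ppc_stop("format", "led_index, x, y must have equal length")
  led_index <- as.integer(led_index)
  dup <- led_index[duplicated(led_index)]
  if (length(dup))
    ppc_stop("format", "duplicate led_index: %s",
             paste(sort(unique(dup)), collapse = ", "))
  missing <- setdiff(seq_len(n), led_index)
  if (length(missing))
    ppc_stop("format", "led_index not complete: missing %s",
             paste(missing, collapse = ", "))
  x <- as.integer(round(x)); y <- as.integer(round(y))
  bad <- which(x < 0 | x >= image_width | y < 0 | y >= image_height)
  if (length(bad))
    ppc_stop("format", "coordinates out of image bounds at led_index %s",
             paste(led_index[bad], collapse = ", "))
  o <- order(led_index)
  m <- data.frame(led_index = led_index[o],
                  label = rep_len(as.character(label), n)[o],
                  x = x[o], y = y[o],
                  stringsAsFactors = FALSE)
  if (min_separation > 0 && n > 1) {
    d <- min(stats::dist(cbind(m$x, m$y)))
    if (d < min_separation)
      ppc_stop("format",
               "closest map entries are %.2f px apart, below the %.2f px separation floor",
               d, min_separation)
  }
  structure(m, class = c("ppc_vector_map", "data.frame"),
            image_width = as.integer(image_width),
            image_height = as.integer(image_height))
}

#' Detect LED spot centres from an all-on calibration frame
#'
#' Automates the brightest-pixel selection that defines the vector map:
#' the frame is converted to grayscale, smoothed with a Gaussian, and
#' local maxima are extracted with a minimum-separation non-maximum
#' suppression (ties broken towards smaller y, then smaller x). Weak
#' surplus maxima (below half the median peak height above background)
#' are pruned to the `expected_count` brightest; a surplus of peaks of
#' comparable height raises an ambiguity error, a deficit a
#' detection-failure error. Detected centres are ordered row-major from
#' the top-left of the image.
#'
#' @param frame A `ppc_frame` taken with all LEDs driven bright.
#' @param expected_count Number of LEDs expected (e.g. 200).
#' @param min_separation Minimum centre-to-centre distance in px
#'   (default 6).
#' @param smooth_sigma Gaussian smoothing sd in px applied before peak
#'   picking (default 1; the spot spread/2 is a good choice).
#' @return A `ppc_vector_map` of `expected_count` integer centres,
#'   unlabeled (see [assign_labels()]).
#' @export
detect_led_centers <- function(frame, expected_count, min_separation = 6,
                               smooth_sigma = 1) {
  px <- frame$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  sm <- if (smooth_sigma > 0) EBImage::gblur(gray, sigma = smooth_sigma) else gray
  bg <- stats::median(sm)
  peak_floor <- bg + 0.2 * (max(sm) - bg)
  if (max(sm) - bg < 5)
    ppc_stop("detection_failure",
             "no LED spots visible: expected %d, found 0 (deficit %d)",
             expected_count, expected_count)
  # 3x3 local maxima above the adaptive floor
  cand <- which(sm > peak_floor, arr.ind = TRUE)
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    r0 <- max(1, r - 1); r1 <- min(h, r + 1)
    c0 <- max(1, c - 1); c1 <- min(w, c + 1)
    sm[r, c] >= max(sm[r0:r1, c0:c1])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L)
    ppc_stop("detection_failure",
             "no local maxima above background: expected %d, found 0 (deficit %d)",
             expected_count, expected_count)
  val <- sm[cand]
  o <- order(-val, cand[, 1], cand[, 2])   # bright first; ties: smaller y then x
  cand <- cand[o, , drop = FALSE]; val <- val[o]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep)) {
      dx <- cand[keep, 2] - cand[i, 2]
      dy <- cand[keep, 1] - cand[i, 1]
      if (min(dx * dx + dy * dy) < min_separation^2) next
    }
    keep <- c(keep, i)
  }
  peaks <- cand[keep, , drop = FALSE]
  pval <- val[keep]
  if (nrow(peaks) < expected_count)
    ppc_stop("detection_failure",
             "detected only %d of %d expected LED centres (deficit %d)",
             nrow(peaks), expected_count, expected_count - nrow(peaks))
  if (nrow(peaks) > expected_count) {
    strong <- (pval - bg) >= 0.5 * stats::median(pval[seq_len(expected_count)] - bg)
    if (sum(strong) > expected_count)
      ppc_stop("ambiguity",
               "detected %d comparable peaks but expected %d; cannot disambiguate",
               sum(strong), expected_count)
    peaks <- peaks[seq_len(expected_count), , drop = FALSE]
  }
  # refine each peak to the argmax pixel of the raw grayscale in a small window
  refined <- t(apply(peaks, 1, function(rc) {
    r <- rc[1]; c <- rc[2]
    rad <- max(1L, as.integer(floor(min_separation / 2)))
    r0 <- max(1, r - rad); r1 <- min(h, r + rad)
    c0 <- max(1, c - rad); c1 <- min(w, c + rad)
    win <- gray[r0:r1, c0:c1, drop = FALSE]
    ij <- which(win == max(win), arr.ind = TRUE)[1, ]
    c(r0 + ij[1] - 1L, c0 + ij[2] - 1L)
  }))
  xs <- refined[, 2] - 1L  # 0-based
  ys <- refined[, 1] - 1L
  ord <- row_major_order(xs, ys, gap = min_separation)
  vector_map(led_index = seq_len(expected_count),
             x = xs[ord], y = ys[ord],
             image_width = w, image_height = h)
}

# Order spot coordinates row-major from the top-left: cluster y values into
# rows wherever the sorted-y gap exceeds `gap`, then sort by x within a row.
row_major_order <- function(x, y, gap) {
  o <- order(y)
  ys <- y[o]
  row_id <- cumsum(c(1, diff(ys) > gap))
  ord <- o[order(row_id, x[o])]
  ord
}

#' Save / load a vector map
#'
#' The on-disk format is a CSV with header `led_index,label,x,y` and
#' integer 0-based pixel coordinates. A `.json` path selects the JSON
#' variant, which additionally embeds the image dimensions. Loading
#' validates completeness of the index set, uniqueness, and image
#' bounds, and reproduces the map exactly.
#'
#' @param map A `ppc_vector_map`.
#' @param path Output/input path (`.csv` or `.json`).
#' @return `load_vector_map()` returns a `ppc_vector_map`.
#' @export
save_vector_map <- function(map, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      image_width = attr(map, "image_width"),
      image_height = attr(map, "image_height"),
      entries = as.data.frame(map)
    ), path, digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(as.data.frame(map), path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname save_vector_map
#' @param image_width,image_height Required when loading the CSV
#'   variant (the JSON variant embeds them).
#' @export
load_vector_map <- function(path, image_width = NULL, image_height = NULL) {
  if (!file.exists(path)) ppc_stop("format", "no such file: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- j$entries
    image_width <- j$image_width; image_height <- j$image_height
  } else {
    # labels like "7.10" must not collapse to the number 7.1
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    for (cc in intersect(c("led_index", "x", "y"), names(df)))
      df[[cc]] <- as.integer(df[[cc]])
    if (is.null(image_width) || is.null(image_height))
      ppc_stop("format", "CSV vector maps need image_width/image_height")
  }
  need <- c("led_index", "x", "y")
  if (!all(need %in% names(df)))
    ppc_stop("format", "vector-map file lacks columns: %s",
             paste(setdiff(need, names(df)), collapse = ", "))
  lab <- if ("label" %in% names(df)) {
    l <- as.character(df$label); l[!nzchar(l) | is.na(l)] <- NA_character_; l
  } else NA_character_
  vector_map(df$led_index, df$x, df$y, image_width, image_height,
             label = lab)
}
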