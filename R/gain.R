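#' Gain-offset matrix from a common-signal test session
#'
#' Manufacturing variation makes each sensor's amplification slightly
#' different. During a common-signal session every electrode is wired to
#' one point on the skin, so all channels see the same signal; the
#' decoded matrix `M_test` then reveals the gain differences, and the
#' offset of every cell from the best (maximum) sensor is stored:
#' `G_test[i,j] = MAX(M_test) - M_test[i,j]`. The maximum-gain sensor
#' gets offset 0, so `min(G) == 0` always.
#'
#' @param m_test A `ppc_sample_matrix` (or plain numeric matrix) of
#'   decoded percentages from the common-signal session.
#' @return A `ppc_gain_matrix`: list with `offsets` (same shape,
#'   non-negative, at least one zero).
#' @examples
#' g <- compute_gain(matrix(c(80, 70, 60, 50), 2, 2, byrow = TRUE))
#' g$offsets  # 0 10 / 20 30
#' @export
compute_gain <- function(m_test) {
  v <- sample_values(m_test)
  if (length(v) == 0L) ppc_stop("domain", "m_test is empty")
  structure(list(offsets = max(v) - v), class = "ppc_gain_matrix")
}

#' Apply gain calibration to an experimental matrix
#'
#' Additive correction as used throughout an experiment:
#' `N[i,j] = M_real[i,j] + G_test[i,j]`. Because percentages cannot
#' exceed full white, results above 100 are clipped to 100 and counted;
#' the count is attached as attribute `n_clipped` on the returned
#' matrix.
#'
#' @param m_real A `ppc_sample_matrix` (or plain matrix) of decoded
#'   percentages from an experiment session.
#' @param g A `ppc_gain_matrix` of the same shape.
#' @return A `ppc_sample_matrix` with `role = "calibrated"` and
#'   attribute `n_clipped`.
#' @export
apply_gain <- function(m_real, g) {
  v <- sample_values(m_real)
  if (!inherits(g, "ppc_gain_matrix"))
    ppc_stop("calibration", "'g' must come from compute_gain()")
  if (!identical(dim(v), dim(g$offsets)))
    ppc_stop("calibration", "shape mismatch: matrix is %s, gain is %s",
             paste(dim(v), collapse = "x"),
             paste(dim(g$offsets), collapse = "x"))
  n <- v + g$offsets
  clipped <- sum(n > 100)
  n <- pmin(n, 100)
  ts <- if (inherits(m_real, "ppc_sample_matrix")) m_real$timestamp else 0
  out <- sample_matrix(n, timestamp = ts, role = "calibrated")
  attr(out, "n_clipped") <- as.integer(clipped)
  out
}

#' Row-vector forms of the gain calibration
#'
#' With LEDs labeled 1..n, calibration can equally run on flat vectors:
#' `G_test[i] = MAX(M_test) - M_test[i]` and `N[i] = M_real[i] +
#' G_test[i]`. Numerically identical to the matrix forms after row-major
#' flattening.
#'
#' @param m_test,m_real Numeric vectors of percentages.
#' @param g Gain-offset vector from `compute_gain_vector()`.
#' @return `compute_gain_vector()`: offset vector with at least one
#'   zero. `apply_gain_vector()`: calibrated vector clipped at 100.
#' @export
compute_gain_vector <- function(m_test) {
  if (!is.numeric(m_test) || length(m_test) == 0L)
    ppc_stop("domain", "m_test must be a non-empty numeric vector")
  max(m_test) - m_test
}

#' @rdname compute_gain_vector
#' @export
apply_gain_vector <- function(m_real, g) {
  if (length(m_real) != length(g))
    ppc_stop("domain", "length mismatch: %d values vs %d offsets",
             length(m_real), length(g))
  pmin(m_real + g, 100)
}

#' Per-cell mean matrix of a session
#'
#' Collapses a decoded series to the single stored value per sensor used
#' as `M_test`: the element-wise mean over the session's frames
#' (averaging suppresses frame noise).
#'
#' @param series A `ppc_signal_series`.
#' @param role Role tag of the result (default `"test"`).
#' @return A `ppc_sample_matrix`.
#' @export
session_mean_matrix <- function(series, role = "test") {
  vals <- Reduce(`+`, lapply(series$matrices, function(m) m$values))
  sample_matrix(vals / length(series$matrices), timestamp = 0, role = role)
}

#' Save / load a gain matrix as a CSV grid
#'
#' @param g A `ppc_gain_matrix`.
#' @param path CSV path (plain grid, no header).
#' @return `load_gain_matrix()` returns a `ppc_gain_matrix`.
#' @export
save_gain_matrix <- function(g, path) {
  utils::write.table(g$offsets, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname save_gain_matrix
#' @export
load_gain_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  if (any(m < 0) || abs(min(m)) > 1e-9)
    ppc_stop("format", "gain offsets must be >= 0 with minimum 0")
  structure(list(offsets = m), class = "ppc_gain_matrix")
}

sample_values <- function(m) {
  if (inherits(m, "ppc_sample_matrix")) m$values
  else if (is.matrix(m) && is.numeric(m)) m
  else ppc_stop("domain", "expected a sample matrix")
}
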