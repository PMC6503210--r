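#' Layout of sensor labels on the LED matrix
#'
#' Describes how the vest's sensors map onto the LED grid. Sensors are
#' labeled `"line.sensor"` (e.g. `"2.5"` = sensor 5 on vertical sensor
#' line 2). The matrix is split into two vertical halves; by default the
#' left half corresponds to the dorsal side of the torso and the right
#' half to the ventral side. Because the correspondence between sensors
#' and LED positions is free as long as it is recorded, the default
#' `label_table` treats each matrix column as one vertical line's LEDs:
#' line = column index (1..`n_cols`), sensor = row index counted from
#' the top of the image, which makes every label unique across the whole
#' matrix. Any other assignment can be supplied as an explicit table.
#'
#' @param n_rows,n_cols Grid dimensions (default 10 x 20).
#' @param halves Named character vector mapping matrix halves to body
#'   side, default `c(left = "dorsal", right = "ventral")`.
#' @param label_table Optional named integer vector: names are labels,
#'   values are LED indices (row-major from top-left). Must be a
#'   bijection onto `1..n_rows*n_cols`.
#' @return An object of class `ppc_layout_spec`.
#' @examples
#' lay <- layout_spec()
#' label_to_index(lay, "1.1")  # 1
#' @export
layout_spec <- function(n_rows = 10L, n_cols = 20L,
                        halves = c(left = "dorsal", right = "ventral"),
                        label_table = NULL) {
  n <- n_rows * n_cols
  if (is.null(label_table)) {
    idx <- seq_len(n)
    col <- (idx - 1L) %% n_cols + 1L
    row <- (idx - 1L) %/% n_cols + 1L
    label_table <- stats::setNames(idx, sprintf("%d.%d", col, row))
  }
  if (length(label_table) != n ||
      !all(sort(as.integer(label_table)) == seq_len(n)))
    ppc_stop("layout",
             "label_table must be a bijection onto led indices 1..%d", n)
  if (anyDuplicated(names(label_table)))
    ppc_stop("layout", "duplicate labels in label_table: %s",
             paste(unique(names(label_table)[duplicated(names(label_table))]),
                   collapse = ", "))
  if (!all(grepl("^[0-9]+\\.[0-9]+$", names(label_table))))
    ppc_stop("layout", "labels must have the form 'line.sensor', e.g. '2.5'")
  if (!identical(sort(names(halves)), c("left", "right")))
    ppc_stop("layout", "'halves' must name the 'left' and 'right' matrix halves")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 halves = halves, label_table = label_table),
            class = "ppc_layout_spec")
}

#' Label lookup helpers
#'
#' `label_to_index()` resolves a `"line.sensor"` label to its LED index
#' (row-major from the top-left); `index_to_label()` is its inverse;
#' `grid_position()` gives the (row, col) grid cell of an LED index.
#'
#' @param layout A [layout_spec()].
#' @param label,led_index Label string / LED index to resolve.
#' @return An integer index, a label string, or a named integer vector
#'   `c(row =, col =)`.
#' @export
label_to_index <- function(layout, label) {
  i <- layout$label_table[label]
  if (any(is.na(i)))
    ppc_stop("layout", "unknown sensor label: %s",
             paste(label[is.na(i)], collapse = ", "))
  as.integer(i)
}

#' @rdname label_to_index
#' @export
index_to_label <- function(layout, led_index) {
  rev_tab <- stats::setNames(names(layout$label_table),
                             layout$label_table)
  lab <- rev_tab[as.character(led_index)]
  if (any(is.na(lab)))
    ppc_stop("layout", "led_index out of layout range: %s",
             paste(led_index[is.na(lab)], collapse = ", "))
  unname(lab)
}

#' @rdname label_to_index
#' @export
grid_position <- function(layout, led_index) {
  n <- layout$n_rows * layout$n_cols
  if (any(led_index < 1 | led_index > n))
    ppc_stop("layout", "led_index must lie in 1..%d", n)
  c(row = (led_index - 1L) %/% layout$n_cols + 1L,
    col = (led_index - 1L) %% layout$n_cols + 1L)
}

#' Attach sensor labels to a vector map
#'
#' Carries the layout's label for every LED index onto the map, so that
#' the inverse lookup label -> (x, y) is total. Idempotent.
#'
#' @param map A `ppc_vector_map`.
#' @param layout A [layout_spec()] covering all of the map's indices.
#' @return The labeled `ppc_vector_map`.
#' @export
assign_labels <- function(map, layout) {
  n <- nrow(map)
  if (layout$n_rows * layout$n_cols != n)
    ppc_stop("layout", "layout covers %d LEDs but the map has %d entries",
             layout$n_rows * layout$n_cols, n)
  map$label <- index_to_label(layout, map$led_index)
  map
}

#' Pixel coordinate of a labeled sensor
#'
#' @param map A labeled `ppc_vector_map`.
#' @param layout A [layout_spec()].
#' @param label Sensor label, e.g. `"2.5"`.
#' @return Named vector `c(x =, y =)`, 0-based pixels.
#' @export
label_coordinate <- function(map, layout, label) {
  i <- label_to_index(layout, label)
  row <- map[map$led_index == i, ]
  c(x = row$x, y = row$y)
}

#' Wiring ledger of the vest
#'
#' Bookkeeping check of the physical harness: each of the vest's
#' vertical sensor lines takes two supply wires and each sensor one
#' signal wire, so the default rig (16 lines, 200 sensors) needs
#' 2 x 16 + 200 = 232 connections.
#'
#' @param n_lines Number of vertical sensor lines (default 16: 8 per
#'   body side).
#' @param n_sensors Number of sensors (default 200).
#' @return Integer total connection count.
#' @export
wiring_connections <- function(n_lines = 16L, n_sensors = 200L) {
  as.integer(2L * n_lines + n_sensors)
}
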