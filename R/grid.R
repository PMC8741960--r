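# The counting grid: evenly spaced interior lines laid over the SAD image,
# and enumeration of grid-skeleton intersections.

#' Define the counting grid
#'
#' `n_lines_per_axis` evenly spaced interior lines per axis at 0-based
#' positions `round(k * H / (n + 1))`, `k = 1..n` (and likewise for the
#' width). With the default 10 + 10 lines this is the classical "10 x 10
#' grid" overlay used for functional capillary counting. Line positions
#' are 0-based pixel offsets from the image origin; none lie on the image
#' border.
#'
#' @param image_shape `c(rows, cols)` of the image the grid sits on.
#' @param n_lines_per_axis Lines per axis (default 10).
#' @return A list of class `grid_spec`: `n_lines_per_axis`, `line_rows`,
#'   `line_cols` (0-based positions), `image_shape`.
#' @export
make_grid <- function(image_shape, n_lines_per_axis = 10L) {
  n <- as.integer(n_lines_per_axis)
  if (n < 1L) stop("`n_lines_per_axis` must be >= 1", call. = FALSE)
  image_shape <- as.integer(image_shape[1:2])
  if (any(image_shape < n + 1L)) {
    stop("image too small for the requested grid", call. = FALSE)
  }
  k <- seq_len(n)
  structure(
    list(
      n_lines_per_axis = n,
      line_rows = as.integer(round(k * image_shape[1] / (n + 1))),
      line_cols = as.integer(round(k * image_shape[2] / (n + 1))),
      image_shape = image_shape
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d + %d lines on %d x %d px\n",
              x$n_lines_per_axis, x$n_lines_per_axis,
              x$image_shape[1], x$image_shape[2]))
  invisible(x)
}

#' Enumerate grid-skeleton intersections
#'
#' For each grid line, skeleton pixels lying on that line are clustered
#' into runs along the line; runs separated by less than `min_separation`
#' px merge (this absorbs the skeleton jitter of one thick vessel crossing
#' a line, at the price of fusing genuinely adjacent capillaries — a
#' documented free parameter). Each merged run yields one record at its
#' centroid, snapped to the nearest skeleton pixel on the line. Crossings
#' are counted independently per axis.
#'
#' @param skeleton Logical matrix (1-px-wide centerlines).
#' @param grid A [make_grid()] spec.
#' @param min_separation Merge distance along a line, px.
#' @return data.frame with columns `axis` ("horizontal"/"vertical" grid
#'   line), `line_index` (1-based within axis), `row`, `col` (0-based pixel
#'   location of the crossing).
#' @export
find_intersections <- function(skeleton, grid, min_separation = 5) {
  stopifnot(is.matrix(skeleton), inherits(grid, "grid_spec"))
  recs <- list()
  k <- 1L
  snap <- function(centroid, pix) pix[which.min(abs(pix - centroid))]
  for (i in seq_along(grid$line_rows)) {
    r0 <- grid$line_rows[i]
    cols0 <- which(skeleton[r0 + 1L, ]) - 1L
    for (ctr in merge_positions(cols0, min_separation)) {
      recs[[k]] <- data.frame(axis = "horizontal", line_index = i,
                              row = r0, col = snap(ctr, cols0))
      k <- k + 1L
    }
  }
  for (i in seq_along(grid$line_cols)) {
    c0 <- grid$line_cols[i]
    rows0 <- which(skeleton[, c0 + 1L]) - 1L
    for (ctr in merge_positions(rows0, min_separation)) {
      recs[[k]] <- data.frame(axis = "vertical", line_index = i,
                              row = snap(ctr, rows0), col = c0)
      k <- k + 1L
    }
  }
  if (length(recs) == 0) {
    return(data.frame(axis = character(0), line_index = integer(0),
                      row = integer(0), col = integer(0)))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
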