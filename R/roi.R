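#' Polygonal region of interest
#'
#' A closed simple polygon delineating an anatomical region (e.g. the corpus
#' callosum) in pixel coordinates. Vertices are `(row, col)` pairs in the same
#' 1-based pixel-center units as [channel_image()] rasters; the polygon is
#' closed implicitly (the last vertex connects back to the first).
#'
#' @param vertices numeric matrix or data.frame with two columns `(row, col)`,
#'   at least 3 vertices; the polygon must be simple (non-self-intersecting)
#'   with non-zero area.
#' @param name free-text region name.
#' @return An object of class `PolygonROI`.
#' @examples
#' roi <- polygon_roi(cbind(c(.5, .5, 10.5, 10.5), c(.5, 10.5, 10.5, .5)))
#' roi_area_px(roi)  # 100
#' @export
polygon_roi <- function(vertices, name = "roi") {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("'vertices' must have two columns (row, col)")
  if (nrow(v) < 3L) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(v))) stop("vertices must be finite")
  if (abs(shoelace_area(v)) <= .Machine$double.eps * max(abs(v), 1))
    stop("degenerate polygon: zero area")
  if (!polygon_is_simple(v)) stop("polygon is self-intersecting")
  colnames(v) <- c("row", "col")
  structure(list(vertices = v, name = as.character(name)[1L]),
            class = "PolygonROI")
}

#' @export
print.PolygonROI <- function(x, ...) {
  cat(sprintf("PolygonROI '%s': %d vertices, area %.4g px^2\n",
              x$name, nrow(x$vertices), roi_area_px(x)))
  invisible(x)
}

# signed shoelace area (px^2); positive for counter-clockwise vertex order
shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

#' Exact polygon area from the shoelace formula
#' @param roi a [polygon_roi()].
#' @return Area in squared pixels.
#' @export
roi_area_px <- function(roi) abs(shoelace_area(roi$vertices))

# proper-crossing test for every non-adjacent edge pair; O(n^2), n is small
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # edges sharing the closing vertex
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      q1 <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
      d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
# py/px: point rows/cols; v: vertex matrix. Points exactly on an edge follow
# the half-open crossing convention (deterministic, but callers should avoid
# placing pixel centers on polygon edges).
points_in_polygon <- function(py, px, v) {
  n <- nrow(v)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1L]; xi <- v[i, 2L]
    yj <- v[j, 1L]; xj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI to a binary mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. The mask's physical area is
#' `sum(mask) * pixel_size_um^2`.
#'
#' @param roi a [polygon_roi()].
#' @param shape integer vector `c(nrow, ncol)` of the target raster.
#' @return Logical matrix of dimension `shape`.
#' @export
roi_mask <- function(roi, shape) {
  stopifnot(inherits(roi, "PolygonROI"), length(shape) == 2L)
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  ctr <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  matrix(points_in_polygon(ctr$row, ctr$col, roi$vertices), nr, nc)
}

#' Read / write polygon ROIs as JSON vertex lists
#'
#' The on-disk format is a JSON object `{"name": ..., "vertices": [[r, c],
#' ...]}` in 1-based pixel units — trivially diffable and language-neutral.
#'
#' @param path JSON file path.
#' @return `read_roi` returns a [polygon_roi()].
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  x <- jsonlite::fromJSON(path)
  polygon_roi(x$vertices, name = if (is.null(x$name)) "roi" else x$name)
}

#' @rdname read_roi
#' @param roi a [polygon_roi()] to serialize.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(
    list(name = roi$name,
         vertices = unname(apply(roi$vertices, 1L, c, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convenience rectangle ROI
#'
#' Axis-aligned rectangle whose mask covers exactly the pixel block
#' `rows[1]:rows[2]` by `cols[1]:cols[2]` (corners sit half a pixel outside
#' the outermost pixel centers).
#'
#' @param rows,cols integer ranges `c(first, last)` of covered pixels.
#' @param name region name.
#' @export
rect_roi <- function(rows, cols, name = "rect") {
  r0 <- rows[1L] - 0.5; r1 <- rows[2L] + 0.5
  c0 <- cols[1L] - 0.5; c1 <- cols[2L] + 0.5
  polygon_roi(cbind(c(r0, r0, r1, r1), c(c0, c1, c1, c0)), name = name)
}
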