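#' Area of a simple polygon
#'
#' Computes the area enclosed by a simple (non-self-intersecting) polygon
#' given in nanometre coordinates, using the shoelace formula, and reports
#' it in square micrometres. Vertex order (clockwise or counter-clockwise)
#' does not matter.
#'
#' @param polygon Two-column numeric matrix (or data.frame) of vertices,
#'   columns x and y in nm. The polygon is closed implicitly; do not repeat
#'   the first vertex.
#' @return Area in um^2 (scalar).
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' polygon_area(sq)  # 1 um^2
#' @export
polygon_area <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (!is.numeric(polygon) || ncol(polygon) != 2L) {
    stop("`polygon` must be a two-column numeric matrix of (x, y) vertices")
  }
  if (nrow(polygon) < 3L) {
    stop("a polygon needs at least 3 vertices, got ", nrow(polygon))
  }
  if (any(!is.finite(polygon))) stop("polygon vertices must be finite")
  x <- polygon[, 1L]
  y <- polygon[, 2L]
  xs <- c(x[-1L], x[1L])
  ys <- c(y[-1L], y[1L])
  area_nm2 <- abs(sum(x * ys - xs * y)) / 2
  area_nm2 / 1e6
}

#' Nuclear region of interest
#'
#' Wraps a polygon outline of a nucleus (vertices in nm) together with its
#' derived area in um^2. The polygon must be simple; self-intersecting
#' outlines are rejected.
#'
#' @param polygon Two-column numeric matrix of vertices in nm.
#' @param check_simple Verify the polygon does not self-intersect
#'   (O(n^2) segment test; disable for very large trusted outlines).
#' @return An object of class `nucleus_roi` with elements `polygon` (matrix,
#'   nm) and `area` (um^2).
#' @export
nucleus_roi <- function(polygon, check_simple = TRUE) {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (ncol(polygon) != 2L || nrow(polygon) < 3L) {
    stop("ROI polygon must be an n x 2 matrix with n >= 3")
  }
  if (any(!is.finite(polygon))) stop("ROI polygon vertices must be finite")
  if (check_simple && !.polygon_is_simple(polygon)) {
    stop("ROI polygon is self-intersecting; a simple polygon is required")
  }
  area <- polygon_area(polygon)
  if (area <= 0) stop("ROI polygon has zero area")
  structure(list(polygon = polygon, area = area), class = "nucleus_roi")
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("<nucleus_roi> %d vertices, area %.3f um^2\n",
              nrow(x$polygon), x$area))
  invisible(x)
}

#' Regular-polygon disk ROI
#'
#' Convenience constructor for an approximately circular nuclear outline:
#' a regular n-gon inscribed in a circle. The default (radius 5 um, 64
#' vertices) mimics the projected area of an isolated nucleus.
#'
#' @param radius Circle radius, nm.
#' @param n_vertices Number of polygon vertices.
#' @param center Circle centre, nm.
#' @return A [nucleus_roi()].
#' @export
disk_roi <- function(radius = 5000, n_vertices = 64L, center = c(0, 0)) {
  stopifnot(radius > 0, n_vertices >= 3L)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  nucleus_roi(cbind(center[1L] + radius * cos(th),
                    center[2L] + radius * sin(th)),
              check_simple = FALSE)
}

# Simple-polygon test: no two non-adjacent edges intersect.
.polygon_is_simple <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- .cross(p3, p4, p1); d2 <- .cross(p3, p4, p2)
    d3 <- .cross(p1, p2, p3); d4 <- .cross(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  if (n > 400L) return(TRUE)  # skip quadratic check for big outlines
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n - 1L && i == 1L) next
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

.cross <- function(o, a, b) {
  (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
}

#' Convex hull of localizations as an ROI
#'
#' Default stand-in for a nuclear outline when none was drawn: the convex
#' hull of all localization coordinates. Appropriate when pores cover the
#' imaged nuclear surface densely, so the hull closely follows the imaged
#' area.
#'
#' @param table A [localization_table()].
#' @return A [nucleus_roi()].
#' @export
hull_roi <- function(table) {
  xy <- cbind(table$x, table$y)
  if (nrow(xy) < 3L) stop("need at least 3 localizations for a hull ROI")
  h <- grDevices::chull(xy)
  nucleus_roi(xy[h, , drop = FALSE], check_simple = FALSE)
}

#' Read / write an ROI polygon as JSON
#'
#' The on-disk format is a JSON array of `[x_nm, y_nm]` vertex pairs.
#'
#' @param path File path.
#' @return `read_roi()` returns a [nucleus_roi()].
#' @export
read_roi <- function(path) {
  v <- jsonlite::fromJSON(path)
  nucleus_roi(matrix(as.numeric(v), ncol = 2L,
                     dimnames = NULL, byrow = FALSE))
}

#' @rdname read_roi
#' @param roi A [nucleus_roi()].
#' @export
write_roi <- function(roi, path) {
  stopifnot(inherits(roi, "nucleus_roi"))
  m <- unname(roi$polygon)
  jsonlite::write_json(m, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

# Point-in-polygon (TRUE for points inside), via mgcv's in/out test.
.points_in_polygon <- function(xy, polygon) {
  bnd <- rbind(polygon, polygon[1L, ])
  mgcv::in.out(bnd, xy)
}
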