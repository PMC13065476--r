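#' Vector feature set (wind-farm polygons, port points)
#'
#' A minimal feature container: each feature has a unique id, a name, a
#' geometry (closed polygon ring or point, as a two-column lon/lat matrix)
#' and a named list of attributes (e.g. wind-farm `status`).
#'
#' @param features List of features, each a list with elements `id`, `name`,
#'   `geometry` (n x 2 lon/lat matrix; polygons need not repeat the first
#'   vertex), `type` (`"polygon"` or `"point"`), and `attributes` (named
#'   list, possibly empty).
#' @return A `vector_set`.
#' @export
vector_set <- function(features) {
  ids <- vapply(features, function(f) as.character(f$id), character(1))
  if (anyDuplicated(ids))
    stop("feature ids must be unique", call. = FALSE)
  for (f in features) {
    if (!f$type %in% c("polygon", "point"))
      stop("geometry type must be 'polygon' or 'point'", call. = FALSE)
    g <- f$geometry
    if (!is.matrix(g) || ncol(g) != 2)
      stop("geometry must be a two-column lon/lat matrix", call. = FALSE)
    if (f$type == "polygon") {
      if (nrow(unique_ring(g)) < 3)
        stop("polygon needs at least 3 distinct vertices", call. = FALSE)
      if (ring_self_intersects(unique_ring(g)))
        stop(sprintf("polygon '%s' is self-intersecting", f$id),
             call. = FALSE)
    }
  }
  structure(list(features = features), class = "vector_set")
}

#' @export
print.vector_set <- function(x, ...) {
  tp <- vapply(x$features, `[[`, character(1), "type")
  cat(sprintf("vector_set: %d features (%d polygons, %d points)\n",
              length(x$features), sum(tp == "polygon"), sum(tp == "point")))
  invisible(x)
}

#' @export
length.vector_set <- function(x) length(x$features)

# drop a repeated closing vertex
unique_ring <- function(g) {
  if (nrow(g) > 1 && all(g[1, ] == g[nrow(g), ])) g[-nrow(g), , drop = FALSE]
  else g
}

# segment-crossing test between non-adjacent edges (planar, adequate for the
# small lon/lat polygons handled here)
ring_self_intersects <- function(g) {
  n <- nrow(g)
  if (n < 4) return(FALSE)
  seg <- cbind(g, g[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (segments_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a, b) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
                         (q[2] - p[2]) * (r[1] - p[1])
  p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Points-in-polygon test
#'
#' Which of the supplied lon/lat points fall inside a polygon feature.
#' Wraps [mgcv::in.out()] on the closed ring.
#'
#' @param pts n x 2 matrix of lon/lat points.
#' @param polygon Polygon geometry (vertex matrix) or a polygon feature.
#' @return Logical vector of length n.
#' @export
points_in_polygon <- function(pts, polygon) {
  if (is.list(polygon)) polygon <- polygon$geometry
  ring <- unique_ring(polygon)
  ring <- rbind(ring, ring[1, ])
  mgcv::in.out(ring, matrix(as.numeric(pts), ncol = 2))
}

#' Spherical polygon area
#'
#' Area of a polygon feature on the sphere (R = 6371 km), in km^2, via
#' [geosphere::areaPolygon()].
#'
#' @param polygon Polygon geometry or feature.
#' @return Area in km^2.
#' @export
polygon_area_km2 <- function(polygon) {
  if (is.list(polygon)) polygon <- polygon$geometry
  suppressWarnings(
    geosphere::areaPolygon(unique_ring(polygon), r = 6371000)) / 1e6
}

polygon_centroid <- function(polygon) {
  if (is.list(polygon)) polygon <- polygon$geometry
  colMeans(unique_ring(polygon))
}
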