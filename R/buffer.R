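# Route buffers. A buffer is the set of points within `radius_m` of the
# route polyline (round caps and joins by construction). It is represented
# implicitly by (polyline, radius); membership tests use exact
# point-to-polyline distances, and an explicit polygon outline is obtained
# on demand by contouring the distance field.

#' Buffer a walking route
#'
#' Builds the planar Euclidean buffer of a route polyline in its local
#' metric frame. The buffer captures the micro-scale environment of the
#' trip; the study convention is a 25-m radius.
#'
#' @param route a `walking_trip` or a numeric matrix of (x, y) vertices in
#'   metres with at least 2 rows.
#' @param radius_m buffer radius in metres (> 0), default 25.
#' @return a `route_buffer` object.
#' @export
buffer_route <- function(route, radius_m = 25) {
  if (inherits(route, "walking_trip")) route <- route$route
  route <- as.matrix(route)
  if (nrow(route) < 2L) stop("buffer_route: route must have at least 2 vertices")
  if (!is.finite(radius_m) || radius_m <= 0)
    stop("buffer_route: radius_m must be positive")
  # decimated route for membership queries (error well below both the
  # buffer scale and typical GPS noise)
  route_s <- simplify_polyline(route, tol = min(1.5, radius_m / 16))
  structure(list(route = route, route_s = route_s, radius_m = radius_m),
            class = "route_buffer")
}

#' @export
print.route_buffer <- function(x, ...) {
  cat(sprintf("<route_buffer> radius %.1f m, route %d vertices, length %.1f m\n",
              x$radius_m, nrow(x$route), polyline_length(x$route)))
  invisible(x)
}

#' Points inside a route buffer
#'
#' Closed-region membership: points exactly on the boundary count as inside.
#'
#' @param buffer a `route_buffer`.
#' @param pts two-column matrix of (x, y) in metres.
#' @return logical vector.
#' @export
buffer_contains <- function(buffer, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  route <- buffer$route_s %||% buffer$route
  r <- buffer$radius_m
  out <- logical(nrow(pts))
  near <- pts[, 1] >= min(route[, 1]) - r & pts[, 1] <= max(route[, 1]) + r &
          pts[, 2] >= min(route[, 2]) - r & pts[, 2] <= max(route[, 2]) + r
  if (any(near))
    out[near] <- dist_to_polyline(pts[near, , drop = FALSE], route) <= r + 1e-9
  out
}

# Distance-field grid over the buffer bounding box.
buffer_distance_field <- function(buffer, resolution_m) {
  r <- buffer$radius_m
  route <- simplify_polyline(buffer$route, tol = min(0.5, resolution_m / 4))
  pad <- r + 3 * resolution_m
  xs <- seq(min(route[, 1]) - pad, max(route[, 1]) + pad, by = resolution_m)
  ys <- seq(min(route[, 2]) - pad, max(route[, 2]) + pad, by = resolution_m)
  g <- as.matrix(expand.grid(xs, ys))
  d <- matrix(dist_to_polyline(g, route), nrow = length(xs))
  list(x = xs, y = ys, z = d)
}

#' Buffer outline polygon
#'
#' Contours the distance-to-route field at the buffer radius, yielding one
#' or more rings (a looping route can enclose holes).
#'
#' @param buffer a `route_buffer`.
#' @param resolution_m contouring grid step; default radius/50.
#' @return list of closed (x, y) matrices, attribute `hole` marking rings
#'   that bound excluded pockets.
#' @export
buffer_polygon <- function(buffer, resolution_m = buffer$radius_m / 50) {
  f <- buffer_distance_field(buffer, resolution_m)
  cl <- grDevices::contourLines(f$x, f$y, f$z, levels = buffer$radius_m)
  rings <- lapply(cl, function(l) {
    m <- cbind(x = l$x, y = l$y)
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
  hole <- vapply(rings, function(m) {
    ctr <- colMeans(m[-nrow(m), , drop = FALSE])
    d <- dist_to_polyline(matrix(ctr, ncol = 2), buffer$route)
    d > buffer$radius_m  # region inside the ring lies outside the buffer
  }, logical(1))
  attr(rings, "hole") <- hole
  rings
}

#' Buffer area
#'
#' Shoelace area of the contoured outline (holes subtracted). For a straight
#' route of length L this converges on the capsule area 2rL + pi r^2.
#'
#' @inheritParams buffer_polygon
#' @return area in square metres.
#' @export
buffer_area <- function(buffer, resolution_m = buffer$radius_m / 50) {
  rings <- buffer_polygon(buffer, resolution_m)
  hole <- attr(rings, "hole")
  a <- vapply(rings, polygon_area, numeric(1))
  sum(a * ifelse(hole, -1, 1))
}
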