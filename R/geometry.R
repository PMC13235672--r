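# Planar and spherical geometry primitives. All trip-level geometry is done
# in a local metric frame (equirectangular about a reference latitude) so
# that buffers, grids and distances are ordinary Euclidean objects; only
# between-fix geodesic distances use the sphere.

EARTH_RADIUS_M <- 6371000
DEG_M <- pi * EARTH_RADIUS_M / 180  # metres per degree of arc, 111194.9266

#' Haversine great-circle distance
#'
#' Geodesic distance between points on a sphere of radius 6,371,000 m.
#'
#' @param p1,p2 numeric vectors `c(lat, lon)` in degrees, or two-column
#'   matrices (lat, lon) of equal length for vectorised use.
#' @return distance(s) in metres.
#' @export
haversine_m <- function(p1, p2) {
  if (is.null(dim(p1))) p1 <- matrix(p1, ncol = 2)
  if (is.null(dim(p2))) p2 <- matrix(p2, ncol = 2)
  lat1 <- p1[, 1]; lon1 <- p1[, 2]
  lat2 <- p2[, 1]; lon2 <- p2[, 2]
  if (any(!is.finite(c(lat1, lon1, lat2, lon2))))
    stop("haversine_m: non-finite coordinates")
  if (any(abs(lat1) > 90) || any(abs(lat2) > 90))
    stop("haversine_m: latitude outside [-90, 90]")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Local metric frame
#'
#' Equirectangular mapping centred at (`lat0`, `lon0`): x east, y north,
#' both in metres. Adequate at neighbourhood scale, where the mapping error
#' is far below GPS noise.
#' @param lat0,lon0 reference point in degrees.
#' @export
local_frame <- function(lat0, lon0) {
  structure(list(lat0 = lat0, lon0 = lon0), class = "local_frame")
}

#' @rdname local_frame
#' @param lat,lon coordinates in degrees.
#' @param frame a `local_frame`.
#' @export
lonlat_to_local <- function(lat, lon, frame) {
  cbind(x = (lon - frame$lon0) * DEG_M * cos(frame$lat0 * pi / 180),
        y = (lat - frame$lat0) * DEG_M)
}

#' @rdname local_frame
#' @param x,y coordinates in metres.
#' @export
local_to_lonlat <- function(x, y, frame) {
  cbind(lat = frame$lat0 + y / DEG_M,
        lon = frame$lon0 + x / (DEG_M * cos(frame$lat0 * pi / 180)))
}

# Distance from points (px, py) to segment (ax,ay)-(bx,by); vectorised over
# points for one segment.
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Minimum distance from each point to a polyline (matrix of x,y vertices).
dist_to_polyline <- function(pts, route) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(route)
  if (n == 1L) return(sqrt((pts[, 1] - route[1, 1])^2 + (pts[, 2] - route[1, 2])^2))
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1L)) {
    d <- pmin(d, point_segment_dist(pts[, 1], pts[, 2],
                                    route[i, 1], route[i, 2],
                                    route[i + 1L, 1], route[i + 1L, 2]))
  }
  d
}

# Minimum distance between segment p1-p2 and segments given by consecutive
# rows of `route` (vectorised over the route). 0 when they intersect.
seg_polyline_dist <- function(p1, p2, route) {
  n <- nrow(route)
  if (n < 2L) return(min(point_segment_dist(route[, 1], route[, 2],
                                            p1[1], p1[2], p2[1], p2[2])))
  a1x <- route[-n, 1]; a1y <- route[-n, 2]
  a2x <- route[-1, 1]; a2y <- route[-1, 2]
  # proper intersection test (orientation signs)
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(p1[1], p1[2], p2[1], p2[2], a1x, a1y)
  d2 <- o(p1[1], p1[2], p2[1], p2[2], a2x, a2y)
  d3 <- o(a1x, a1y, a2x, a2y, p1[1], p1[2])
  d4 <- o(a1x, a1y, a2x, a2y, p2[1], p2[2])
  if (any(d1 * d2 <= 0 & d3 * d4 <= 0)) return(0)
  # otherwise the minimum is endpoint-to-segment
  min(point_segment_dist(a1x, a1y, p1[1], p1[2], p2[1], p2[2]),
      point_segment_dist(a2x, a2y, p1[1], p1[2], p2[1], p2[2]),
      min(dist_to_polyline(rbind(p1, p2), route)))
}

# Ray-casting point-in-polygon (closed or open ring), vectorised over points.
# Boundary points may fall either side; callers needing closed-region
# semantics combine with a distance test.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Shoelace area (absolute value).
polygon_area <- function(poly) {
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Separating-axis intersection test for two convex polygons (touching counts).
convex_intersects <- function(a, b) {
  axes_of <- function(p) {
    n <- nrow(p)
    if (all(p[1, ] == p[n, ])) { p <- p[-n, , drop = FALSE]; n <- n - 1L }
    e <- p[c(2:n, 1), ] - p
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes_of(a), axes_of(b))) {
    for (i in seq_len(nrow(ax))) {
      pa <- a %*% ax[i, ]; pb <- b %*% ax[i, ]
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
    }
  }
  TRUE
}

# Douglas-Peucker polyline simplification (used to speed up grid queries;
# tolerance well below the grid scale so results are unaffected).
simplify_polyline <- function(route, tol = 1) {
  n <- nrow(route)
  if (n <= 2L) return(route)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    idx <- (i + 1L):(j - 1L)
    d <- point_segment_dist(route[idx, 1], route[idx, 2],
                            route[i, 1], route[i, 2], route[j, 1], route[j, 2])
    k <- which.max(d)
    if (d[k] > tol) {
      m <- idx[k]; keep[m] <- TRUE
      stack <- c(stack, list(c(i, m)), list(c(m, j)))
    }
  }
  route[keep, , drop = FALSE]
}

polyline_length <- function(route) {
  if (nrow(route) < 2L) return(0)
  sum(sqrt(rowSums((route[-1, , drop = FALSE] - route[-nrow(route), , drop = FALSE])^2)))
}
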