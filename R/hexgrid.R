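# Hexagonal exposure grid. Flat-topped hexagons with circumscribed-circle
# diameter `diameter_m` (vertex-to-vertex width), tiling the plane:
# column spacing 1.5 R, row spacing sqrt(3) R, odd columns offset by half a
# row. Cells are the Voronoi regions of their centres, which makes
# point-to-cell assignment a nearest-centre lookup.

#' Build a hexagonal grid over a rectangular extent
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param diameter_m vertex-to-vertex cell diameter, default 25.
#' @return a `hex_grid` with cell centres, axial indices and circumradius.
#' @export
build_hex_grid <- function(extent, diameter_m = 25) {
  stopifnot(length(extent) == 4)
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("build_hex_grid: degenerate extent")
  R <- diameter_m / 2
  dx <- 1.5 * R
  dy <- sqrt(3) * R
  is <- seq(floor((extent[1] - R) / dx), ceiling((extent[2] + R) / dx))
  js <- seq(floor((extent[3] - R) / dy) - 1L, ceiling((extent[4] + R) / dy))
  idx <- expand.grid(i = is, j = js)
  cx <- idx$i * dx
  cy <- idx$j * dy + ifelse(idx$i %% 2 == 0, 0, dy / 2)
  keep <- cx >= extent[1] - R & cx <= extent[2] + R &
          cy >= extent[3] - R & cy <= extent[4] + R
  grid <- structure(list(
    cell_id = seq_len(sum(keep)),
    i = idx$i[keep], j = idx$j[keep],
    cx = cx[keep], cy = cy[keep],
    R = R, extent = extent
  ), class = "hex_grid")
  # axial (i, j) -> cell_id lookup
  key <- paste(grid$i, grid$j)
  grid$lookup <- stats::setNames(grid$cell_id, key)
  grid
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d cells, diameter %.1f m, extent [%g, %g] x [%g, %g]\n",
              length(x$cell_id), 2 * x$R, x$extent[1], x$extent[2],
              x$extent[3], x$extent[4]))
  invisible(x)
}

#' Hexagon polygon of one cell
#'
#' @param grid a `hex_grid`.
#' @param cell_id cell identifier.
#' @return closed 7 x 2 matrix of vertices.
#' @export
hex_cell_polygon <- function(grid, cell_id) {
  k <- match(cell_id, grid$cell_id)
  ang <- seq(0, 2 * pi, length.out = 7)
  cbind(x = grid$cx[k] + grid$R * cos(ang),
        y = grid$cy[k] + grid$R * sin(ang))
}

# Area of one cell: 3*sqrt(3)/2 * R^2.
hex_cell_area <- function(grid) 3 * sqrt(3) / 2 * grid$R^2

#' Cell containing each point
#'
#' Nearest-centre assignment (hex cells are the Voronoi regions of their
#' centres).
#'
#' @param grid a `hex_grid`.
#' @param pts two-column (x, y) matrix in metres.
#' @return integer cell ids (NA outside the grid).
#' @export
cell_for_point <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  R <- grid$R; dx <- 1.5 * R; dy <- sqrt(3) * R
  n <- nrow(pts)
  best_id <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  i0 <- round(pts[, 1] / dx)
  for (di in -1:1) {
    i <- i0 + di
    off <- ifelse(i %% 2 == 0, 0, dy / 2)
    j0 <- round((pts[, 2] - off) / dy)
    for (dj in -1:1) {
      j <- j0 + dj
      id <- grid$lookup[paste(i, j)]
      cxx <- i * dx
      cyy <- j * dy + off
      d <- (pts[, 1] - cxx)^2 + (pts[, 2] - cyy)^2
      upd <- !is.na(id) & d < best_d
      best_id[upd] <- id[upd]
      best_d[upd] <- d[upd]
    }
  }
  best_id
}

#' Grid cells intersecting a route buffer
#'
#' Exact closed intersection: a cell is returned when its hexagon comes
#' within the buffer radius of the route polyline (shared boundary counts).
#' Also accepts an explicit convex polygon in place of a buffer.
#'
#' @param grid a `hex_grid`.
#' @param buffer a `route_buffer`, or a closed convex (x, y) polygon matrix.
#' @return integer vector of cell ids (no duplicates, ascending).
#' @export
cells_for_route <- function(grid, buffer) {
  if (inherits(buffer, "route_buffer")) {
    r <- buffer$radius_m
    route <- buffer$route_s %||% buffer$route
    bb <- c(range(route[, 1]), range(route[, 2]))
    pre <- which(grid$cx >= bb[1] - r - grid$R & grid$cx <= bb[2] + r + grid$R &
                 grid$cy >= bb[3] - r - grid$R & grid$cy <= bb[4] + r + grid$R)
    if (!length(pre)) {
      warning("cells_for_route: buffer outside grid extent")
      return(integer(0))
    }
    dc <- dist_to_polyline(cbind(grid$cx[pre], grid$cy[pre]), route)
    sure <- dc <= r + 1e-9                 # centre inside buffer
    out <- dc > r + grid$R                 # whole hexagon provably outside
    maybe <- which(!sure & !out)
    hit <- sure
    if (length(maybe)) {
      # sample the hexagon (vertices, edge midpoints, spoke midpoints);
      # together with the centre these cover the hexagon to within
      # `cover`, so dmin > r + cover proves the cell misses the buffer
      ang12 <- (0:11) * pi / 6
      rad12 <- grid$R * ifelse((0:11) %% 2 == 0, 1, sqrt(3) / 2)
      sx <- c(rad12 * cos(ang12), grid$R / 2 * cos(ang12[c(TRUE, FALSE)]))
      sy <- c(rad12 * sin(ang12), grid$R / 2 * sin(ang12[c(TRUE, FALSE)]))
      ns <- length(sx)
      cover <- 0.3 * grid$R
      samp <- cbind(rep(grid$cx[pre[maybe]], each = ns) + rep(sx, length(maybe)),
                    rep(grid$cy[pre[maybe]], each = ns) + rep(sy, length(maybe)))
      ds <- dist_to_polyline(samp, route)
      dmin <- pmin(tapply(ds, rep(seq_along(maybe), each = ns), min),
                   dc[maybe])
      hit[maybe[dmin <= r + 1e-9]] <- TRUE
      amb <- maybe[dmin > r + 1e-9 & dmin <= r + cover]
      for (k in amb) {
        poly <- hex_cell_polygon(grid, grid$cell_id[pre[k]])
        d <- Inf
        for (e in seq_len(nrow(poly) - 1L))
          d <- min(d, seg_polyline_dist(poly[e, ], poly[e + 1L, ], route))
        if (d <= r + 1e-9 ||
            any(point_in_polygon(route[, 1], route[, 2], poly)))
          hit[k] <- TRUE
      }
    }
    ids <- grid$cell_id[pre[hit]]
  } else {
    poly <- as.matrix(buffer)
    bb <- c(range(poly[, 1]), range(poly[, 2]))
    pre <- which(grid$cx >= bb[1] - grid$R & grid$cx <= bb[2] + grid$R &
                 grid$cy >= bb[3] - grid$R & grid$cy <= bb[4] + grid$R)
    if (!length(pre)) {
      warning("cells_for_route: polygon outside grid extent")
      return(integer(0))
    }
    hit <- vapply(pre, function(k) {
      convex_intersects(hex_cell_polygon(grid, grid$cell_id[k]), poly)
    }, logical(1))
    ids <- grid$cell_id[pre[hit]]
  }
  sort(unique(ids))
}
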