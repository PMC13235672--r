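# Haversine distances, route buffers and the hexagonal grid.

test_that("haversine matches closed-form degree arcs and basic properties", {
  # one degree of arc at the equator: 2*pi*R/360
  expect_equal(haversine_m(c(0, 0), c(0, 1)), 2 * pi * 6371000 / 360,
               tolerance = 0.01 / 111194)
  # quarter meridian: pi*R/2
  expect_equal(haversine_m(c(0, 0), c(90, 0)), pi * 6371000 / 2,
               tolerance = 1 / 1e7)
  expect_identical(haversine_m(c(38.7, -9.1), c(38.7, -9.1)), 0)
  # symmetry on random pairs
  set.seed(1)
  for (i in 1:20) {
    p <- runif(2, -80, 80); q <- runif(2, -80, 80)
    expect_equal(haversine_m(p, q), haversine_m(q, p))
    expect_gte(haversine_m(p, q), 0)
  }
  expect_error(haversine_m(c(91, 0), c(0, 0)), "latitude")
})

test_that("haversine agrees with an independent implementation", {
  skip_if_not_installed("geosphere")
  set.seed(2)
  for (i in 1:25) {
    p <- c(runif(1, -85, 85), runif(1, -180, 180))
    q <- c(runif(1, -85, 85), runif(1, -180, 180))
    expect_equal(haversine_m(p, q),
                 geosphere::distHaversine(rev(p), rev(q), r = 6371000),
                 tolerance = 1e-9)
  }
})

test_that("straight-route buffer area matches the capsule closed form", {
  L <- 1000; r <- 25
  b <- buffer_route(cbind(seq(0, L, by = 10), 0), r)
  expect_equal(buffer_area(b), L * 2 * r + pi * r^2, tolerance = 0.005)
})

test_that("buffer construction validates its inputs", {
  expect_error(buffer_route(cbind(0, 0), 25), "2 vertices")
  expect_error(buffer_route(cbind(0:1, 0), 0), "positive")
  expect_error(buffer_route(cbind(0:1, 0), -5), "positive")
})

test_that("buffer contains every route vertex and respects the radius", {
  set.seed(3)
  route <- cbind(cumsum(runif(50, -5, 10)), cumsum(runif(50, -8, 8)))
  b <- buffer_route(route, 25)
  expect_true(all(buffer_contains(b, route)))
  # points just inside / outside a straight segment
  b2 <- buffer_route(cbind(c(0, 100), c(0, 0)), 25)
  expect_true(buffer_contains(b2, cbind(50, 24.9)))
  expect_true(buffer_contains(b2, cbind(50, 25)))     # boundary is closed
  expect_false(buffer_contains(b2, cbind(50, 25.2)))
})

test_that("hex grid tiles the extent with 25-m cells", {
  g <- build_hex_grid(c(0, 500, 0, 500), 25)
  # every cell polygon has vertex-to-vertex diameter 25
  for (id in sample(g$cell_id, 10)) {
    poly <- hex_cell_polygon(g, id)[1:6, ]
    d <- max(dist(poly))
    expect_equal(d, 25, tolerance = 1e-9)
  }
  # total tiled area covers the extent to within one boundary ring
  a_cells <- length(g$cell_id) * 3 * sqrt(3) / 2 * 12.5^2
  ring <- 4 * 500 * 25   # generous one-cell boundary ring allowance
  expect_lt(abs(a_cells - 500^2), ring + 4 * 25^2)
  expect_error(build_hex_grid(c(0, 0, 0, 100)), "degenerate")
})

test_that("nearest-centre cell assignment matches polygon membership", {
  g <- build_hex_grid(c(0, 300, 0, 300), 25)
  set.seed(4)
  pts <- cbind(runif(200, 20, 280), runif(200, 20, 280))
  ids <- cell_for_point(g, pts)
  for (k in sample(200, 25)) {
    poly <- hex_cell_polygon(g, ids[k])
    # the assigned cell's polygon contains the point (or it lies on an edge)
    inside <- walkscape:::point_in_polygon(pts[k, 1], pts[k, 2], poly)
    on_edge <- walkscape:::dist_to_polyline(pts[k, , drop = FALSE], poly) < 1e-6
    expect_true(inside || on_edge)
  }
})

test_that("cells intersecting a hexagon-shaped region are the cell plus its six neighbours", {
  g <- build_hex_grid(c(0, 300, 0, 300), 25)
  cid <- cell_for_point(g, c(150, 150))
  got <- cells_for_route(g, hex_cell_polygon(g, cid))
  expect_length(got, 7)
  expect_true(cid %in% got)
})

test_that("cells_for_route matches a brute-force geometric oracle", {
  g <- build_hex_grid(c(0, 400, 0, 400), 25)
  set.seed(5)
  route <- cbind(cumsum(runif(60, -6, 12)) + 120, cumsum(runif(60, -9, 9)) + 200)
  buf <- buffer_route(route, 25)
  fast <- cells_for_route(g, buf)
  brute <- integer(0)
  for (id in g$cell_id) {
    poly <- hex_cell_polygon(g, id)
    gx <- seq(min(poly[, 1]), max(poly[, 1]), by = 0.4)
    gy <- seq(min(poly[, 2]), max(poly[, 2]), by = 0.4)
    pts <- as.matrix(expand.grid(gx, gy))
    keep <- walkscape:::point_in_polygon(pts[, 1], pts[, 2], poly) |
      walkscape:::dist_to_polyline(pts, poly) < 0.25
    pts <- pts[keep, , drop = FALSE]
    if (any(walkscape:::dist_to_polyline(pts, buf$route_s) <= 25))
      brute <- c(brute, id)
  }
  expect_identical(fast, brute)
})

test_that("disjoint buffers yield no cells, with a warning outside the grid", {
  g <- build_hex_grid(c(0, 200, 0, 200), 25)
  buf <- buffer_route(cbind(c(5000, 5100), c(5000, 5000)), 25)
  expect_warning(got <- cells_for_route(g, buf), "outside")
  expect_length(got, 0)
})

test_that("union of returned cells covers the buffer", {
  g <- build_hex_grid(c(0, 400, 0, 400), 25)
  set.seed(6)
  route <- cbind(cumsum(runif(40, 0, 8)) + 100, cumsum(runif(40, -6, 6)) + 200)
  buf <- buffer_route(route, 25)
  ids <- cells_for_route(g, buf)
  # random points inside the buffer must land in a returned cell
  pts <- cbind(runif(500, 80, 350), runif(500, 120, 300))
  pts <- pts[buffer_contains(buf, pts), , drop = FALSE]
  expect_gt(nrow(pts), 50)
  expect_true(all(cell_for_point(g, pts) %in% ids))
})

test_that("local frame round-trips coordinates", {
  fr <- local_frame(38.72, -9.14)
  set.seed(7)
  xy <- cbind(runif(50, -2000, 2000), runif(50, -2000, 2000))
  ll <- local_to_lonlat(xy[, 1], xy[, 2], fr)
  back <- lonlat_to_local(ll[, 1], ll[, 2], fr)
  expect_equal(unname(back), unname(xy), tolerance = 1e-9)
})
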