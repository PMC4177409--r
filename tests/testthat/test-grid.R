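test_that("fishnet dimensions cover the bounding box by the ceiling rule", {
  net <- make_fishnet(c(0, 0, 1, 1), 0.5)
  expect_equal(c(net$n_rows, net$n_cols), c(2L, 2L))
  net2 <- make_fishnet(c(0, 0, 1.1, 1), 0.5)
  expect_equal(c(net2$n_rows, net2$n_cols), c(2L, 3L))
  expect_equal(net2$crs_label, "ETRS89-geographic")
  expect_error(make_fishnet(c(0, 0, 0, 1), 0.5), "degenerate")

  # cell count equals an independent double-loop construction over the
  # synthetic subregion's bounding box
  bbox <- c(12.0, 40.0, 19.5, 45.6)
  d <- 0.45
  net3 <- make_fishnet(bbox, d)
  n_brute <- 0L
  r <- 0L
  while (bbox[2] + r * d < bbox[4] - 1e-9) {
    c0 <- 0L
    while (bbox[1] + c0 * d < bbox[3] - 1e-9) { n_brute <- n_brute + 1L; c0 <- c0 + 1L }
    r <- r + 1L
  }
  expect_equal(net3$n_rows * net3$n_cols, n_brute)
})

test_that("cell_of follows the half-open convention with outer-edge closure", {
  net <- make_fishnet(c(0, 0, 2, 2), 1)
  expect_equal(cell_of(net, 0.5, 0.5)[1, c("row", "col")],
               tibble::tibble(row = 0L, col = 0L))
  # a point on a shared edge belongs to the cell it lower-bounds
  expect_equal(cell_of(net, 1.0, 0.5)$col, 1L)
  # outer top/right boundary belongs to the last row/column
  expect_equal(cell_of(net, 2.0, 2.0)[1, c("row", "col")],
               tibble::tibble(row = 1L, col = 1L))
  expect_true(is.na(cell_of(net, 2.5, 0.5)$cell_id))
})

test_that("cell_of agrees with a brute-force bounds scan on random points", {
  net <- make_fishnet(c(3.2, 40.1, 7.7, 44.3), 0.45)
  set.seed(17)
  lon <- runif(1000, 2.9, 8.0)
  lat <- runif(1000, 39.8, 44.6)
  got <- cell_of(net, lon, lat)
  brute <- brute_cell_of(net, lon, lat)
  expect_equal(got$row, brute[, 1])
  expect_equal(got$col, brute[, 2])
})

test_that("point_in_polygon matches geometry on squares and counts boundaries", {
  sq <- unit_square()
  expect_true(point_in_polygon(0.5, 0.5, sq))
  expect_true(point_in_polygon(0, 0.5, sq))   # boundary counts
  expect_false(point_in_polygon(1.5, 0.5, sq))
  # even-odd with a hole
  holed <- list(unit_square(0, 0, 4), unit_square(1, 1, 2))
  expect_true(point_in_polygon(0.5, 0.5, holed))
  expect_false(point_in_polygon(2, 2, holed))
  expect_true(point_in_polygon(1, 2, holed))  # hole boundary counts
})

test_that("clipping marks cells intersecting the polygon, boundary touches included", {
  net <- make_fishnet(c(0, 0, 2, 2), 1)
  full <- clip_to_subregion(net, unit_square(0, 0, 2))
  expect_equal(full$total_cells, 4L)
  point_like <- clip_to_subregion(net, cbind(c(0.4, 0.6, 0.5), c(0.4, 0.4, 0.6)))
  expect_equal(point_like$total_cells, 1L)
  expect_error(clip_to_subregion(net, cbind(c(0, 1), c(0, 1))), "geometry")
})

test_that("clipping agrees with brute-force rectangle-polygon intersection", {
  set.seed(23)
  for (trial in 1:5) {
    # random convex polygon: convex hull of random points
    pts <- cbind(runif(12, 0.2, 3.8), runif(12, 0.2, 3.8))
    hull <- pts[chull(pts), ]
    net <- make_fishnet(c(0, 0, 4, 4), 0.7)
    grid <- clip_to_subregion(net, hull)
    # independent oracle: dense point sampling of each cell rectangle plus
    # vertex membership
    brute <- apply(as.matrix(grid$cells[, c("lon0", "lat0", "lon1", "lat1")]), 1,
      function(b) {
        gx <- seq(b[1], b[3], length.out = 15)
        gy <- seq(b[2], b[4], length.out = 15)
        g <- expand.grid(gx, gy)
        any(point_in_polygon(g[, 1], g[, 2], hull)) ||
          any(hull[, 1] >= b[1] & hull[, 1] <= b[3] &
              hull[, 2] >= b[2] & hull[, 2] <= b[4])
      })
    expect_equal(grid$cells$in_subregion, unname(brute))
  }
})

test_that("clipping is monotone under polygon enlargement", {
  net <- make_fishnet(c(0, 0, 5, 5), 0.8)
  small <- clip_to_subregion(net, unit_square(1, 1, 1.5))
  big <- clip_to_subregion(net, unit_square(0.5, 0.5, 3))
  expect_gte(big$total_cells, small$total_cells)
  expect_true(all(small$cells$in_subregion <= big$cells$in_subregion))
})

test_that("polygons and grids round-trip through GeoJSON", {
  poly <- subregion_polygon("islands")
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_polygon(poly, path)
  back <- read_geojson_polygon(path)
  expect_equal(length(back), 2L)
  # the reader strips the explicit closing vertex
  expect_equal(unname(back[[1]]), unname(poly[[1]][-nrow(poly[[1]]), ]),
               tolerance = 1e-12)

  net <- make_fishnet(c(0, 0, 1, 1), 0.5)
  grid <- clip_to_subregion(net, unit_square())
  gpath <- withr::local_tempfile(fileext = ".geojson")
  write_grid_geojson(grid, gpath)
  gj <- jsonlite::fromJSON(gpath, simplifyVector = FALSE)
  expect_equal(length(gj$features), 4L)
  expect_true(all(sapply(gj$features, function(f) isTRUE(f$properties$in_subregion))))
})
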