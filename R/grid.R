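#' Build a fishnet grid
#'
#' Constructs the regular reference grid (fishnet) covering a bounding
#' box, in ETRS89 geographic coordinates. The grid is built in angular
#' measures with a 1:1 cell aspect ratio; the default cell side of 0.45
#' degrees corresponds to roughly 50 km meridionally at Mediterranean
#' latitudes. The origin is the bounding box's lower-left corner (it can
#' be overridden to reproduce an externally supplied net) and the column
#' and row counts are the smallest that cover the box.
#'
#' @param bbox Numeric `c(lon_min, lat_min, lon_max, lat_max)` with
#'   `min < max` on both axes.
#' @param cell_size_deg Positive angular cell side in decimal degrees
#'   (default 0.45).
#' @param origin Optional `c(lon, lat)` lower-left corner overriding the
#'   bounding box corner.
#' @return An object of class `fishnet`: a list with `origin_lon`,
#'   `origin_lat`, `cell_size_deg`, `n_rows`, `n_cols` and `crs_label`
#'   (`"ETRS89-geographic"`).
#' @examples
#' make_fishnet(c(0, 0, 1, 1), 0.5)
#' @export
make_fishnet <- function(bbox, cell_size_deg = 0.45, origin = NULL) {
  check_that(length(bbox) == 4 && all(is.finite(bbox)), "bbox must be 4 finite numbers")
  check_that(bbox[1] < bbox[3] && bbox[2] < bbox[4],
             "degenerate bbox: need min < max on both axes")
  check_that(is_scalar_number(cell_size_deg) && cell_size_deg > 0,
             "cell_size_deg must be a positive scalar")
  origin <- origin %||% bbox[1:2]
  # tiny tolerance so a box that is an exact multiple of the cell size
  # does not gain a spurious row/column to floating-point error
  eps <- sqrt(.Machine$double.eps)
  n_cols <- max(1L, as.integer(ceiling((bbox[3] - origin[1]) / cell_size_deg - eps)))
  n_rows <- max(1L, as.integer(ceiling((bbox[4] - origin[2]) / cell_size_deg - eps)))
  structure(
    list(origin_lon = origin[1], origin_lat = origin[2],
         cell_size_deg = cell_size_deg, n_rows = n_rows, n_cols = n_cols,
         crs_label = "ETRS89-geographic"),
    class = "fishnet"
  )
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("Fishnet %d rows x %d cols, cell %.4g deg, origin (%.4g, %.4g), %s\n",
              x$n_rows, x$n_cols, x$cell_size_deg, x$origin_lon, x$origin_lat,
              x$crs_label))
  invisible(x)
}

#' Locate points in fishnet cells
#'
#' Cells are half-open on the right and top (`[low, high)`), so a point
#' on a shared edge belongs to the cell of which that edge is the
#' lower/left bound; points exactly on the net's outer top or right
#' boundary belong to the last row or column. Points outside the net get
#' `NA`.
#'
#' @param fishnet A [make_fishnet()] object.
#' @param lon,lat Point coordinates (vectorised).
#' @return A tibble with integer columns `row`, `col` (0-based) and
#'   `cell_id` (`"r<row>_c<col>"`, `NA` outside the net).
#' @examples
#' net <- make_fishnet(c(0, 0, 2, 2), 1)
#' cell_of(net, c(0.5, 1.0, 2.5), c(0.5, 0.5, 0.5))
#' @export
cell_of <- function(fishnet, lon, lat) {
  d <- fishnet$cell_size_deg
  col <- floor((lon - fishnet$origin_lon) / d)
  row <- floor((lat - fishnet$origin_lat) / d)
  # outer top/right boundary closure
  on_right <- lon == fishnet$origin_lon + fishnet$n_cols * d
  on_top <- lat == fishnet$origin_lat + fishnet$n_rows * d
  col[on_right] <- fishnet$n_cols - 1
  row[on_top] <- fishnet$n_rows - 1
  outside <- col < 0 | col >= fishnet$n_cols | row < 0 | row >= fishnet$n_rows
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  tibble::tibble(
    row = as.integer(row), col = as.integer(col),
    cell_id = ifelse(is.na(row), NA_character_,
                     sprintf("r%d_c%d", as.integer(row), as.integer(col)))
  )
}

# ---- planar geometry primitives -------------------------------------------
# Polygons are rings given as two-column (lon, lat) matrices or data
# frames, implicitly closed; a list of rings is interpreted under the
# even-odd rule (holes and multi-part subregions).

as_rings <- function(polygon) {
  if (is.data.frame(polygon) || is.matrix(polygon)) polygon <- list(polygon)
  rings <- purrr::map(polygon, function(r) {
    r <- as.matrix(as.data.frame(r)[, 1:2])
    storage.mode(r) <- "double"
    check_that(nrow(r) >= 3 && all(is.finite(r)),
               "invalid geometry: a ring needs at least 3 finite vertices")
    # drop an explicit closing vertex
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    check_that(nrow(r) >= 3, "invalid geometry: degenerate ring")
    r
  })
  rings
}

on_segment <- function(px, py, ax, ay, bx, by, tol = 1e-12) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  scale <- max(abs(c(ax, ay, bx, by, px, py)), 1)
  if (abs(cross) > tol * scale) return(FALSE)
  px >= min(ax, bx) - tol && px <= max(ax, bx) + tol &&
    py >= min(ay, by) - tol && py <= max(ay, by) + tol
}

#' Test whether points fall inside a polygon
#'
#' Even-odd ray-casting test; points exactly on a boundary count as
#' inside.
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param polygon A ring (two-column lon/lat matrix or data frame,
#'   implicitly closed) or a list of rings interpreted under the
#'   even-odd rule.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  rings <- as_rings(polygon)
  purrr::map2_lgl(lon, lat, function(px, py) {
    inside <- FALSE
    for (ring in rings) {
      n <- nrow(ring)
      j <- n
      for (i in seq_len(n)) {
        ax <- ring[i, 1]; ay <- ring[i, 2]
        bx <- ring[j, 1]; by <- ring[j, 2]
        if (on_segment(px, py, ax, ay, bx, by)) return(TRUE)
        if ((ay > py) != (by > py)) {
          xint <- ax + (py - ay) / (by - ay) * (bx - ax)
          if (px < xint) inside <- !inside
        }
        j <- i
      }
    }
    inside
  })
}

segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    s <- max(abs(c(a, b, c)), 1)
    if (abs(v) < 1e-12 * s) 0 else sign(v)
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  if (d1 != d2 && d3 != d4) return(TRUE)
  (d1 == 0 && on_segment(p1[1], p1[2], q1[1], q1[2], q2[1], q2[2])) ||
  (d2 == 0 && on_segment(p2[1], p2[2], q1[1], q1[2], q2[1], q2[2])) ||
  (d3 == 0 && on_segment(q1[1], q1[2], p1[1], p1[2], p2[1], p2[2])) ||
  (d4 == 0 && on_segment(q2[1], q2[2], p1[1], p1[2], p2[1], p2[2]))
}

# rectangle given as c(x0, y0, x1, y1); boundary touch counts
rect_intersects_polygon <- function(rect, polygon) {
  rings <- as_rings(polygon)
  x0 <- rect[1]; y0 <- rect[2]; x1 <- rect[3]; y1 <- rect[4]
  # any polygon vertex inside the rectangle (inclusive)
  for (ring in rings) {
    if (any(ring[, 1] >= x0 & ring[, 1] <= x1 &
            ring[, 2] >= y0 & ring[, 2] <= y1)) return(TRUE)
  }
  # any rectangle corner inside the polygon
  corners_x <- c(x0, x1, x1, x0)
  corners_y <- c(y0, y0, y1, y1)
  if (any(point_in_polygon(corners_x, corners_y, rings))) return(TRUE)
  # any edge crossing
  rect_edges <- list(
    list(c(x0, y0), c(x1, y0)), list(c(x1, y0), c(x1, y1)),
    list(c(x1, y1), c(x0, y1)), list(c(x0, y1), c(x0, y0))
  )
  for (ring in rings) {
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      a <- ring[i, ]; b <- ring[j, ]
      for (e in rect_edges) {
        if (segments_intersect(a, b, e[[1]], e[[2]])) return(TRUE)
      }
      j <- i
    }
  }
  FALSE
}

# ---------------------------------------------------------------------------

#' Clip a fishnet to a subregion polygon
#'
#' Marks each grid cell as belonging to the subregion when its rectangle
#' intersects the subregion polygon (a boundary touch counts), and
#' counts the total cells of the subregion grid - the denominator of the
#' spatial-coverage statistic.
#'
#' @param fishnet A [make_fishnet()] object.
#' @param polygon Subregion polygon: a ring or list of rings (see
#'   [point_in_polygon()]), e.g. from [read_geojson_polygon()] or
#'   [subregion_polygon()].
#' @return An object of class `subregion_grid`: list with the `fishnet`,
#'   the `polygon`, a `cells` tibble (`row`, `col`, `cell_id`, bounds
#'   `lon0`/`lat0`/`lon1`/`lat1`, `in_subregion`) and `total_cells`, the
#'   count of cells intersecting the subregion.
#' @export
clip_to_subregion <- function(fishnet, polygon) {
  rings <- as_rings(polygon)
  d <- fishnet$cell_size_deg
  cells <- tidyr::expand_grid(
    row = seq_len(fishnet$n_rows) - 1L,
    col = seq_len(fishnet$n_cols) - 1L
  )
  cells <- dplyr::mutate(
    cells,
    cell_id = sprintf("r%d_c%d", .data$row, .data$col),
    lon0 = fishnet$origin_lon + .data$col * d,
    lat0 = fishnet$origin_lat + .data$row * d,
    lon1 = .data$lon0 + d,
    lat1 = .data$lat0 + d,
    in_subregion = purrr::pmap_lgl(
      list(.data$lon0, .data$lat0, .data$lon1, .data$lat1),
      function(lon0, lat0, lon1, lat1)
        rect_intersects_polygon(c(lon0, lat0, lon1, lat1), rings)
    )
  )
  structure(
    list(fishnet = fishnet, polygon = rings, cells = cells,
         total_cells = sum(cells$in_subregion)),
    class = "subregion_grid"
  )
}

#' @export
print.subregion_grid <- function(x, ...) {
  print(x$fishnet)
  cat(sprintf("  %d of %d cells intersect the subregion\n",
              x$total_cells, nrow(x$cells)))
  invisible(x)
}

#' Read a polygon from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, a `Feature`, or a
#' `FeatureCollection` whose first feature carries the subregion
#' boundary. Coordinates are longitude/latitude (ETRS89/WGS84
#' geographic).
#'
#' @param path GeoJSON file path.
#' @return A list of rings usable wherever a polygon is accepted.
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (identical(g$type, "FeatureCollection")) g <- g$features[[1]]
  if (identical(g$type, "Feature")) g <- g$geometry
  rings <- switch(
    g$type,
    Polygon = g$coordinates,
    MultiPolygon = purrr::flatten(g$coordinates),
    abort(paste0("unsupported GeoJSON geometry type: ", g$type))
  )
  purrr::map(rings, function(r) {
    m <- do.call(rbind, purrr::map(r, unlist))
    colnames(m) <- c("lon", "lat")
    m
  }) |> as_rings()
}

#' Write a polygon to GeoJSON
#'
#' @param polygon A ring or list of rings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygon <- function(polygon, path) {
  rings <- as_rings(polygon)
  coords <- purrr::map(rings, function(r) {
    r <- rbind(r, r[1, ])  # close the ring
    purrr::map(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  })
  gj <- list(
    type = "Feature",
    properties = list(crs = "ETRS89-geographic"),
    geometry = list(type = "Polygon", coordinates = coords)
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a grid as a GeoJSON FeatureCollection
#'
#' One polygon feature per cell, with properties `row`, `col` and
#' `in_subregion`.
#'
#' @param grid A `subregion_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_geojson <- function(grid, path) {
  features <- purrr::pmap(
    grid$cells,
    function(row, col, cell_id, lon0, lat0, lon1, lat1, in_subregion, ...) {
      list(
        type = "Feature",
        properties = list(row = row, col = col, cell_id = cell_id,
                          in_subregion = in_subregion),
        geometry = list(type = "Polygon", coordinates = list(list(
          c(lon0, lat0), c(lon1, lat0), c(lon1, lat1), c(lon0, lat1),
          c(lon0, lat0)
        )))
      )
    }
  )
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
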