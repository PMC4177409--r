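#' Spatial coverage percentage
#'
#' Share of a subregion's grid cells containing at least one assessed
#' datum for a category, as a percentage rounded half-up to one
#' decimal.
#'
#' @param n_cells_with_data Number of cells with data,
#'   `0 <= n_cells_with_data <= n_total_cells`.
#' @param n_total_cells Total cells of the subregion grid, `>= 1`.
#' @return Percentage with one decimal.
#' @examples
#' spatial_coverage(42, 51)
#' @export
spatial_coverage <- function(n_cells_with_data, n_total_cells) {
  check_that(all(n_total_cells >= 1), "n_total_cells must be at least 1")
  check_that(all(n_cells_with_data >= 0 & n_cells_with_data <= n_total_cells),
             "need 0 <= n_cells_with_data <= n_total_cells")
  round_half_up(100 * n_cells_with_data / n_total_cells, 1)
}

#' Exceedance frequency
#'
#' Number of measurements above the regulatory level and their share of
#' all observed data - the regulatory-exceedance indicator of the
#' Descriptor 9 assessment.
#'
#' @param codes Non-empty vector of datum codes in `{1, 2}`.
#' @return A one-row tibble with `n`, `n_exceed`, `pct_exceed` (one
#'   decimal, half-up).
#' @examples
#' exceedance_frequency(c(rep(1, 15), 2))
#' @export
exceedance_frequency <- function(codes) {
  check_that(length(codes) >= 1, "exceedance frequency of empty input")
  check_that(all(codes %in% c(1L, 2L)), "codes must be 1 or 2")
  n_exceed <- sum(codes == 2L)
  tibble::tibble(
    n = length(codes),
    n_exceed = n_exceed,
    pct_exceed = round_half_up(100 * n_exceed / length(codes), 1)
  )
}

pct_pair <- function(n_within, n_total) {
  if (n_total == 0) return(c(NA_real_, NA_real_))
  c(round_half_up(100 * n_within / n_total, 1),
    round_half_up(100 * (n_total - n_within) / n_total, 1))
}

#' Summary statistics per regulatory category
#'
#' Builds the per-category summary of one subregion: spatial coverage
#' and the percentages of data, stations and cells within/outside the
#' regulatory limits, with the underlying counts. Categories in the
#' catalog with no data are emitted with `NA` percentages (rendered as
#' "-" by [format_summary_table()]) and are excluded from denominators.
#'
#' @param coded Coded measurement tibble ([code_measurements()]).
#' @param stations Station assessments ([assess_stations()]).
#' @param cells Cell assessments ([assess_cells()]).
#' @param grid `subregion_grid` providing the total-cells denominator.
#' @param catalog Regulatory catalog (rows define the output order).
#' @param subregion Label for the subregion column.
#' @return A tibble, one row per catalog category: `subregion`,
#'   `category_code`, `spatial_coverage_pct`, `pct_data_within`,
#'   `pct_data_outside`, `pct_stations_within`, `pct_stations_outside`,
#'   `pct_cells_within`, `pct_cells_outside`, `n_data`, `n_stations`,
#'   `n_cells_with_data`, `n_total_cells`.
#' @export
summarize_assessment <- function(coded, stations, cells, grid,
                                 catalog = msfd_catalog(),
                                 subregion = "synthetic") {
  total_cells <- grid$total_cells
  check_that(total_cells >= 1, "subregion grid has no cells")
  purrr::map(catalog$code, function(code) {
    d <- coded[coded$category_code == code, , drop = FALSE]
    s <- stations[stations$category_code == code, , drop = FALSE]
    cl <- cells[cells$category_code == code, , drop = FALSE]
    n_data <- nrow(d)
    if (n_data == 0) {
      return(tibble::tibble(
        subregion = subregion, category_code = code,
        spatial_coverage_pct = NA_real_,
        pct_data_within = NA_real_, pct_data_outside = NA_real_,
        pct_stations_within = NA_real_, pct_stations_outside = NA_real_,
        pct_cells_within = NA_real_, pct_cells_outside = NA_real_,
        n_data = 0L, n_stations = 0L, n_cells_with_data = 0L,
        n_total_cells = total_cells
      ))
    }
    dp <- pct_pair(sum(d$code == 1L), n_data)
    sp <- pct_pair(sum(s$code == 1L), nrow(s))
    cp <- pct_pair(sum(cl$code == 1L), nrow(cl))
    tibble::tibble(
      subregion = subregion, category_code = code,
      spatial_coverage_pct = spatial_coverage(nrow(cl), total_cells),
      pct_data_within = dp[1], pct_data_outside = dp[2],
      pct_stations_within = sp[1], pct_stations_outside = sp[2],
      pct_cells_within = cp[1], pct_cells_outside = cp[2],
      n_data = n_data, n_stations = nrow(s), n_cells_with_data = nrow(cl),
      n_total_cells = total_cells
    )
  }) |> purrr::list_rbind()
}

#' Render a summary as a fixed-width text table
#'
#' Human-readable layout of the per-category summary: categories as
#' columns, the statistic labels as rows, "-" marking categories without
#' data.
#'
#' @param summary Tibble from [summarize_assessment()].
#' @param drop_empty Drop categories with no data instead of printing
#'   "-" columns.
#' @return A character vector of lines, invisibly printed with `cat()`
#'   when autoprinted.
#' @export
format_summary_table <- function(summary, drop_empty = FALSE) {
  if (drop_empty) summary <- summary[summary$n_data > 0, , drop = FALSE]
  labels <- c(
    spatial_coverage_pct = "% of spatial coverage",
    pct_data_within = "% of data within the limits",
    pct_data_outside = "% of data outside the limits",
    pct_stations_within = "% of station within the limits",
    pct_stations_outside = "% of station outside the limits",
    pct_cells_within = "% of cells within the limits",
    pct_cells_outside = "% of cells outside the limits"
  )
  header <- sprintf("%s (total cells %d)", summary$subregion[1],
                    summary$n_total_cells[1])
  fmt <- function(x) ifelse(is.na(x), "-", formatC(x, format = "fg"))
  cols <- c(header, summary$category_code)
  rows <- purrr::imap(labels, function(lab, field) {
    c(lab, fmt(summary[[field]]))
  })
  mat <- do.call(rbind, c(list(cols), unname(rows)))
  widths <- apply(nchar(mat), 2, max)
  lines <- apply(mat, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  structure(trimws(lines, "right"), class = "msfd9_text_table")
}

#' @export
print.msfd9_text_table <- function(x, ...) {
  cat(x, sep = "\n")
  invisible(x)
}

#' Export cell assessments as a green/red GeoJSON map
#'
#' One polygon feature per assessed cell, property `code` (1 or 2) and
#' `color` (green for cells within the limits, red for cells with equal
#' or majority of exceeding stations). Subregion cells without data can
#' optionally be included with `code = NA`, `color = "no data"`.
#'
#' @param cells Cell assessments for one category
#'   ([assess_cells()], filtered to a single `category_code`).
#' @param grid `subregion_grid` the cells belong to.
#' @param path Output GeoJSON path.
#' @param include_no_data Include unassessed subregion cells.
#' @return `path`, invisibly. Errors if an assessment references a cell
#'   absent from the grid.
#' @export
render_map <- function(cells, grid, path, include_no_data = FALSE) {
  check_that(length(unique(cells$category_code)) <= 1,
             "render_map expects cells of a single category")
  gc <- grid$cells
  dangling <- setdiff(cells$cell_id, gc$cell_id)
  check_that(length(dangling) == 0,
             paste0("assessment references cell(s) absent from the grid: ",
                    paste(dangling, collapse = ", ")))
  merged <- dplyr::left_join(
    dplyr::select(cells, "cell_id", "category_code", "code"),
    dplyr::select(gc, "cell_id", "lon0", "lat0", "lon1", "lat1"),
    by = "cell_id"
  )
  if (include_no_data) {
    empty <- gc[gc$in_subregion & !gc$cell_id %in% cells$cell_id, , drop = FALSE]
    merged <- dplyr::bind_rows(merged, dplyr::transmute(
      empty, cell_id = .data$cell_id,
      category_code = cells$category_code[1] %||% NA_character_,
      code = NA_integer_, lon0 = .data$lon0, lat0 = .data$lat0,
      lon1 = .data$lon1, lat1 = .data$lat1
    ))
  }
  features <- purrr::pmap(
    merged,
    function(cell_id, category_code, code, lon0, lat0, lon1, lat1) {
      color <- if (is.na(code)) "no data" else if (code == 1L) "green" else "red"
      list(
        type = "Feature",
        properties = list(cell_id = cell_id, category_code = category_code,
                          code = code, color = color),
        geometry = list(type = "Polygon", coordinates = list(list(
          c(lon0, lat0), c(lon1, lat0), c(lon1, lat1), c(lon0, lat1),
          c(lon0, lat0)
        )))
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a cell map back from GeoJSON
#'
#' @param path GeoJSON path written by [render_map()].
#' @return A tibble with `cell_id`, `category_code`, `code`, `color`.
#' @export
read_cell_map <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  purrr::map(g$features, function(f) {
    p <- f$properties
    tibble::tibble(
      cell_id = p$cell_id,
      category_code = p$category_code %||% NA_character_,
      code = as.integer(p$code %||% NA_integer_),
      color = p$color
    )
  }) |> purrr::list_rbind()
}

#' Plot a green/red assessment map
#'
#' @param cells Cell assessments for one category.
#' @param grid `subregion_grid` (drawn as the subregion outline plus the
#'   net's in-subregion cells).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(cells, grid, title = NULL) {
  gc <- grid$cells
  merged <- dplyr::inner_join(
    dplyr::select(cells, "cell_id", "code"),
    gc, by = "cell_id"
  )
  outline <- purrr::imap(grid$polygon, function(r, i) {
    tibble::tibble(lon = r[, 1], lat = r[, 2], ring = i)
  }) |> purrr::list_rbind()
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = gc[gc$in_subregion, , drop = FALSE],
      ggplot2::aes(xmin = .data$lon0, xmax = .data$lon1,
                   ymin = .data$lat0, ymax = .data$lat1),
      fill = NA, colour = "grey80", linewidth = 0.2
    ) +
    ggplot2::geom_rect(
      data = merged,
      ggplot2::aes(xmin = .data$lon0, xmax = .data$lon1,
                   ymin = .data$lat0, ymax = .data$lat1,
                   fill = factor(.data$code)),
      colour = "grey40", linewidth = 0.2, alpha = 0.8
    ) +
    ggplot2::geom_polygon(
      data = outline,
      ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$ring),
      fill = NA, colour = "grey30"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`1` = "forestgreen", `2` = "firebrick"),
      labels = c(`1` = "within limits (code 1)", `2` = "exceeding (code 2)"),
      name = NULL, drop = FALSE
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude (\u00b0E)", y = "Latitude (\u00b0N)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot a subregion grid
#'
#' @param object A `subregion_grid`.
#' @param ... Unused.
#' @return A ggplot object showing the fishnet and which cells intersect
#'   the subregion.
#' @method autoplot subregion_grid
#' @export
autoplot.subregion_grid <- function(object, ...) {
  gc <- object$cells
  outline <- purrr::imap(object$polygon, function(r, i) {
    tibble::tibble(lon = r[, 1], lat = r[, 2], ring = i)
  }) |> purrr::list_rbind()
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = gc,
      ggplot2::aes(xmin = .data$lon0, xmax = .data$lon1,
                   ymin = .data$lat0, ymax = .data$lat1,
                   fill = .data$in_subregion),
      colour = "grey70", linewidth = 0.2, alpha = 0.6
    ) +
    ggplot2::geom_polygon(
      data = outline,
      ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$ring),
      fill = NA, colour = "grey20"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "grey95"),
      name = "intersects subregion"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude (\u00b0E)", y = "Latitude (\u00b0N)") +
    ggplot2::theme_minimal()
}
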