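#' Run the full assessment pipeline
#'
#' Convenience wrapper chaining the whole Descriptor 9 workflow on one
#' measurement table: quality control, datum coding, station- and
#' cell-level integration on a fishnet clipped to the subregion, the
#' per-category acceptance-range fits, and the summary table.
#'
#' @param measurements Measurement tibble (e.g. from
#'   [read_measurements()] or [gen_dataset()]).
#' @param polygon Subregion polygon; default the bounding box of the
#'   data (so every record is on the grid).
#' @param catalog Regulatory catalog.
#' @param cell_size_deg Fishnet cell side in decimal degrees.
#' @param mode Year integration mode, `"whole_period"` or
#'   `"single_year"` (see [assess_stations()]).
#' @param subregion Label for the summary rows.
#' @param qc Logical: apply [qc_filter()] first.
#' @param loq_method Censored-value convention.
#' @return A list of class `msfd9_assessment`: `measurements` (kept,
#'   coded), `qc` report, `grid` (`subregion_grid`), `stations`,
#'   `cells`, `acceptance` ([assess_categories()] rows), `summary`
#'   ([summarize_assessment()] rows).
#' @examples
#' m <- gen_dataset(scenario(n_stations = 8, seed = 7))
#' a <- run_assessment(m, polygon = subregion_polygon("basin"))
#' a$summary
#' @export
run_assessment <- function(measurements, polygon = NULL,
                           catalog = msfd_catalog(), cell_size_deg = 0.45,
                           mode = "whole_period", subregion = "synthetic",
                           qc = TRUE, loq_method = "half_loq") {
  if (is.character(polygon)) polygon <- subregion_polygon(polygon)
  bbox <- if (is.null(polygon)) {
    c(min(measurements$lon), min(measurements$lat),
      max(measurements$lon), max(measurements$lat))
  } else {
    polygon_bbox(polygon)
  }
  kept <- if (qc) {
    qc_filter(measurements, catalog, bbox = bbox)
  } else {
    tibble::as_tibble(measurements)
  }
  check_that(nrow(kept) > 0, "no measurements left after quality control")
  net <- make_fishnet(bbox, cell_size_deg)
  grid <- if (is.null(polygon)) {
    clip_to_subregion(net, cbind(
      lon = bbox[c(1, 3, 3, 1)], lat = bbox[c(2, 2, 4, 4)]
    ))
  } else {
    clip_to_subregion(net, polygon)
  }
  coded <- code_measurements(kept, catalog, loq_method)
  stations <- assess_stations(coded, mode = mode)
  cells <- assess_cells(stations, grid)
  acceptance <- assess_categories(kept, catalog, loq_method)
  summary <- summarize_assessment(coded, stations, cells, grid,
                                  catalog = catalog, subregion = subregion)
  structure(
    list(measurements = coded, qc = qc_report(kept), grid = grid,
         stations = stations, cells = cells, acceptance = acceptance,
         summary = summary),
    class = "msfd9_assessment"
  )
}

#' @export
print.msfd9_assessment <- function(x, ...) {
  cat("Descriptor 9 assessment\n")
  cat(sprintf("  %d records, %d station assessments, %d assessed cells (of %d)\n",
              nrow(x$measurements), nrow(x$stations), nrow(x$cells),
              x$grid$total_cells))
  print(format_summary_table(x$summary, drop_empty = TRUE))
  invisible(x)
}

#' Write every pipeline output of an assessment
#'
#' Writes the summary (delimited and fixed-width text), the acceptance
#' report, the cell assessments, and one green/red GeoJSON map per
#' assessed category into a directory. All outputs are deterministic
#' functions of the input assessment.
#'
#' @param assessment A [run_assessment()] result.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_assessment <- function(assessment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(assessment$summary, file.path(dir, "summary.csv"))
  writeLines(format_summary_table(assessment$summary),
             file.path(dir, "summary.txt"))
  write_acceptance_report(assessment$acceptance,
                          file.path(dir, "acceptance.csv"))
  readr::write_csv(assessment$cells, file.path(dir, "cells.csv"))
  for (code in unique(assessment$cells$category_code)) {
    safe <- gsub("[^A-Za-z0-9.-]+", "_", code)
    render_map(
      assessment$cells[assessment$cells$category_code == code, , drop = FALSE],
      assessment$grid, file.path(dir, paste0("map_", safe, ".geojson"))
    )
  }
  invisible(dir)
}
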