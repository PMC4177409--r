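#' Code a concentration against its regulatory level
#'
#' Code 1 (green) marks data not exceeding the threshold level, code 2
#' (red) data above it; a value exactly at the limit does not exceed it
#' and is coded 1.
#'
#' @param concentration Numeric vector of concentrations (after LOQ
#'   handling), in the category's unit.
#' @param limit_value Regulatory level in the same unit (scalar or
#'   vector).
#' @return Integer vector of codes in `{1, 2}`.
#' @examples
#' code_datum(c(0.4, 0.5, 0.51), 0.5)
#' @export
code_datum <- function(concentration, limit_value) {
  check_that(all(is.finite(concentration)) && all(is.finite(limit_value)),
             "concentration and limit must be finite")
  ifelse(concentration <= limit_value, 1L, 2L)
}

#' Add datum codes to a measurement table
#'
#' Joins each record to its regulatory category and codes it 1 (within
#' the limit) or 2 (exceeding). Records whose unit does not match the
#' category's unit are a hard error - unit conversion is not attempted.
#'
#' @param measurements QC-filtered measurement tibble.
#' @param catalog Regulatory catalog.
#' @param loq_method Censored-value convention for [substitute_loq()].
#' @return The tibble with added columns `limit_value` and `code`.
#' @export
code_measurements <- function(measurements, catalog = msfd_catalog(),
                              loq_method = "half_loq") {
  m <- substitute_loq(measurements, loq_method)
  idx <- match(m$category_code, catalog$code)
  check_that(!anyNA(idx), "unresolved category code(s) in measurements")
  mismatch <- m$unit != catalog$limit_unit[idx]
  check_that(!any(mismatch),
             paste0("unit mismatch with the regulatory category in ",
                    sum(mismatch), " record(s)"))
  m$limit_value <- catalog$limit_value[idx]
  m$code <- code_datum(m$concentration, m$limit_value)
  m
}

#' Integrate codes by majority with a precautionary tie rule
#'
#' The integration rule applied at every level of the assessment: the
#' result is the code with the highest frequency; when codes 1 and 2 are
#' equally frequent the result is 2, in compliance with the
#' precautionary principle. A unit with no data is "no data", never
#' coded, so empty input is an error.
#'
#' @param codes Non-empty vector of codes in `{1, 2}`.
#' @return `1L` or `2L`.
#' @examples
#' integrate_codes(c(1, 1, 2))  # majority -> 1
#' integrate_codes(c(1, 2))     # tie -> 2 (precautionary)
#' @export
integrate_codes <- function(codes) {
  check_that(length(codes) >= 1, "cannot integrate an empty set of codes")
  check_that(all(codes %in% c(1L, 2L)), "codes must be 1 or 2")
  n2 <- sum(codes == 2L)
  n1 <- length(codes) - n2
  if (n2 >= n1) 2L else 1L
}

#' Station-level assessment
#'
#' Integrates the datum codes of each station (per regulatory category
#' and, in `"single_year"` mode, per year) into one station code by the
#' same majority/precautionary rule used at cell level.
#'
#' @param coded Measurement tibble with a `code` column, from
#'   [code_measurements()].
#' @param mode `"whole_period"` (default) pools all years of a station
#'   into one station code; `"single_year"` yields one assessment per
#'   station-year, so a station sampled in several years later
#'   contributes several votes to its cell.
#' @return A tibble with one row per station (or station-year) and
#'   category: `station_id`, `category_code`, `lon`, `lat`, `years`,
#'   `code`, `n_data`, `n_exceed`.
#' @export
assess_stations <- function(coded, mode = c("whole_period", "single_year")) {
  mode <- match.arg(mode)
  check_that(nrow(coded) >= 1, "no measurements to assess")
  keys <- c("station_id", "category_code", if (mode == "single_year") "year")
  dplyr::group_by(coded, dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      lon = .data$lon[1], lat = .data$lat[1],
      years = paste(sort(unique(.data$year)), collapse = ","),
      n_data = dplyr::n(),
      n_exceed = sum(.data$code == 2L),
      # assigned last: `code` masks the datum codes once created
      code = integrate_codes(.data$code),
      .groups = "drop"
    )
}

#' Cell-level assessment
#'
#' Assigns station assessments to fishnet cells and integrates the
#' station codes within each cell and category by the
#' majority/precautionary rule. Under the whole-period mode each row of
#' `stations` is one vote; under the single-year upstream mode a station
#' sampled in several years casts one vote per year.
#'
#' @param stations Station assessment tibble from [assess_stations()].
#' @param fishnet A [make_fishnet()] grid (or the `fishnet` of a
#'   `subregion_grid`).
#' @return A tibble with one row per (cell, category): `cell_id`, `row`,
#'   `col`, `category_code`, `code`, `n_stations_code1`,
#'   `n_stations_code2`. Stations falling outside the net are dropped
#'   with a warning.
#' @export
assess_cells <- function(stations, fishnet) {
  if (inherits(fishnet, "subregion_grid")) fishnet <- fishnet$fishnet
  cells <- cell_of(fishnet, stations$lon, stations$lat)
  outside <- is.na(cells$cell_id)
  if (any(outside)) {
    warn(paste0(sum(outside), " station assessment(s) fall outside the fishnet",
                " and are excluded"))
  }
  st <- dplyr::bind_cols(stations[!outside, , drop = FALSE],
                         cells[!outside, , drop = FALSE])
  dplyr::group_by(st, .data$cell_id, .data$row, .data$col, .data$category_code) |>
    dplyr::summarise(
      n_stations_code1 = sum(.data$code == 1L),
      n_stations_code2 = sum(.data$code == 2L),
      # assigned last: `code` masks the station codes once created
      code = integrate_codes(.data$code),
      .groups = "drop"
    )
}
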