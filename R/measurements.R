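measurement_columns <- c(
  "station_id", "lon", "lat", "year", "species", "tissue",
  "category_code", "concentration", "unit", "below_loq", "loq"
)

#' Read a measurement file
#'
#' Reads georeferenced contaminant measurements from delimited text
#' (comma or semicolon separated, UTF-8, header row) and validates each
#' record: coordinates inside valid ranges, non-negative concentration,
#' a limit of quantification present whenever the record is flagged
#' below it, and a category code resolvable in the catalog. Malformed
#' rows are reported, never silently dropped.
#'
#' @param path Path of the measurement file. Required columns:
#'   `station_id`, `lon`, `lat`, `year`, `species`, `tissue`,
#'   `category_code`, `concentration`, `unit`, `below_loq`, `loq`;
#'   an optional `subregion` column is carried through.
#' @param catalog Regulatory catalog the category codes must resolve in;
#'   default the builtin catalog.
#' @param decimal_mark Decimal separator used in the file (`"."` or
#'   `","`; decimal commas require semicolon delimiters).
#' @return A tibble of valid measurements. Rows that fail validation are
#'   attached as a tibble in the `"problems"` attribute (columns `row`,
#'   `rule`, `message`); retrieve it with [measurement_problems()].
#' @seealso [qc_filter()] for the subsequent quality-control step.
#' @export
read_measurements <- function(path, catalog = msfd_catalog(),
                              decimal_mark = ".") {
  check_that(file.exists(path), paste0("measurement file not found: ", path))
  raw <- read_delimited(path, decimal_mark)
  missing <- setdiff(measurement_columns, names(raw))
  check_that(length(missing) == 0,
             paste0("measurement file is missing required column(s): ",
                    paste(missing, collapse = ", ")))
  if (is.character(raw$below_loq)) {
    raw$below_loq <- toupper(trimws(raw$below_loq)) %in% c("TRUE", "T", "1", "YES")
  }
  raw$below_loq <- as.logical(raw$below_loq)
  validate_measurements(raw, catalog)
}

#' Validate measurement records
#'
#' @param measurements A data frame of measurement records.
#' @param catalog Catalog for resolving `category_code`.
#' @return Valid rows as a tibble with a `"problems"` attribute; see
#'   [read_measurements()].
#' @export
validate_measurements <- function(measurements, catalog = msfd_catalog()) {
  m <- tibble::as_tibble(measurements)
  rules <- list(
    lon_range = !is.finite(m$lon) | m$lon < -180 | m$lon > 180,
    lat_range = !is.finite(m$lat) | m$lat < -90 | m$lat > 90,
    negative_concentration = !is.finite(m$concentration) | m$concentration < 0,
    loq_missing = m$below_loq & !is.finite(m$loq),
    unresolved_category = !m$category_code %in% catalog$code
  )
  problems <- purrr::imap(rules, function(bad, rule) {
    bad[is.na(bad)] <- TRUE
    tibble::tibble(row = which(bad), rule = rule,
                   message = paste0("row ", which(bad), ": failed ", rule))
  }) |> purrr::list_rbind()
  keep <- !seq_len(nrow(m)) %in% problems$row
  out <- m[keep, , drop = FALSE]
  attr(out, "problems") <- dplyr::arrange(problems, .data$row)
  out
}

#' Retrieve parse/validation problems
#'
#' @param measurements A tibble returned by [read_measurements()] or
#'   [validate_measurements()].
#' @return A tibble with columns `row`, `rule`, `message` (zero rows if
#'   everything validated).
#' @export
measurement_problems <- function(measurements) {
  attr(measurements, "problems") %||%
    tibble::tibble(row = integer(), rule = character(), message = character())
}

#' Write measurements to delimited text
#'
#' The canonical output dialect: comma delimited, decimal point, UTF-8,
#' full numeric precision (so a write/read round trip is lossless).
#'
#' @param measurements Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  cols <- intersect(c(measurement_columns, "subregion"), names(measurements))
  readr::write_csv(measurements[cols], path)
  invisible(path)
}

#' Quality-control filter for measurement records
#'
#' Applies the record-level quality predicates used before assessment;
#' records unfit for the assessment are removed and fully accounted for.
#' Default predicates: (a) `bbox` - station coordinates fall inside the
#' assessment bounding box; (b) `unit_match` - the record's unit equals
#' the regulatory category's unit; (c) `loq_informative` - a record
#' below the limit of quantification is only kept if that limit does not
#' exceed the regulatory level (otherwise the record cannot inform the
#' compliance decision); (d) `year_window` - sampling year within the
#' assessment window.
#'
#' @param measurements Measurement tibble (validated).
#' @param catalog Regulatory catalog.
#' @param bbox Assessment bounding box `c(lon_min, lat_min, lon_max,
#'   lat_max)`, or `NULL` to disable predicate (a).
#' @param years Two-element integer vector `c(first, last)` of the
#'   assessment window, or `NULL` to disable predicate (d). Default
#'   2006-2012, the MSFD initial-assessment period.
#' @param rules Character vector naming the enabled predicates, any of
#'   `"bbox"`, `"unit_match"`, `"loq_informative"`, `"year_window"`.
#' @return The kept rows, with a [qc_report()] accessible via the
#'   `"qc_report"` attribute. Filtering is total: an empty result is
#'   legal and every removal is attributed to the first violated rule.
#' @examples
#' cat <- msfd_catalog()
#' m <- tibble::tibble(
#'   station_id = "S1", lon = 13, lat = 43, year = 2010L,
#'   species = "Mytilus galloprovincialis", tissue = "soft tissue",
#'   category_code = "Cd 3.2.9", concentration = 0.4,
#'   unit = "mg/kg w.w.", below_loq = FALSE, loq = NA_real_
#' )
#' kept <- qc_filter(m, cat)
#' qc_report(kept)
#' @export
qc_filter <- function(measurements, catalog = msfd_catalog(),
                      bbox = NULL, years = c(2006L, 2012L),
                      rules = c("bbox", "unit_match", "loq_informative",
                                "year_window")) {
  m <- tibble::as_tibble(measurements)
  rules <- match.arg(rules, several.ok = TRUE)
  n <- nrow(m)
  limits <- catalog[match(m$category_code, catalog$code), ]
  fail <- list()
  if ("bbox" %in% rules && !is.null(bbox)) {
    fail$bbox <- m$lon < bbox[1] | m$lon > bbox[3] |
      m$lat < bbox[2] | m$lat > bbox[4]
  }
  if ("unit_match" %in% rules) {
    fail$unit_match <- is.na(limits$limit_unit) | m$unit != limits$limit_unit
  }
  if ("loq_informative" %in% rules) {
    fail$loq_informative <- m$below_loq & m$loq > limits$limit_value
  }
  if ("year_window" %in% rules && !is.null(years)) {
    fail$year_window <- m$year < years[1] | m$year > years[2]
  }
  fail <- purrr::map(fail, function(x) { x[is.na(x)] <- TRUE; x })
  # attribute each removal to the first violated rule
  removed_by <- rep(NA_character_, n)
  for (rule in names(fail)) {
    removed_by[is.na(removed_by) & fail[[rule]]] <- rule
  }
  kept <- m[is.na(removed_by), , drop = FALSE]
  removed_counts <- purrr::map_int(
    setNames(names(fail), names(fail)),
    function(rule) sum(removed_by == rule, na.rm = TRUE)
  )
  report <- structure(
    list(n_input = n, n_kept = nrow(kept), removed_by_rule = removed_counts),
    class = "msfd9_qc_report"
  )
  stopifnot(report$n_input == report$n_kept + sum(report$removed_by_rule))
  attr(kept, "qc_report") <- report
  kept
}

#' Retrieve the quality-control report
#'
#' @param measurements Tibble returned by [qc_filter()].
#' @return An object of class `msfd9_qc_report`: a list with `n_input`,
#'   `n_kept`, and the named removal counts `removed_by_rule` satisfying
#'   `n_input == n_kept + sum(removed_by_rule)`.
#' @export
qc_report <- function(measurements) {
  attr(measurements, "qc_report")
}

#' @export
print.msfd9_qc_report <- function(x, ...) {
  cat("QC report:", x$n_kept, "of", x$n_input, "records kept\n")
  for (rule in names(x$removed_by_rule)) {
    cat("  removed by ", rule, ": ", x$removed_by_rule[[rule]], "\n", sep = "")
  }
  invisible(x)
}

#' Substitute below-LOQ concentrations
#'
#' How censored records (flagged below the limit of quantification)
#' enter the statistics is a convention, not an estimate; the common
#' monitoring convention of substituting half the quantification limit
#' is the default, and every alternative is explicit so the choice stays
#' auditable.
#'
#' @param measurements Measurement tibble.
#' @param method One of `"half_loq"` (default, substitute `loq/2`),
#'   `"loq"`, `"zero"`, `"drop"` (remove censored records).
#' @return The tibble with `concentration` substituted for censored
#'   rows (or censored rows removed under `"drop"`).
#' @export
substitute_loq <- function(measurements,
                           method = c("half_loq", "loq", "zero", "drop")) {
  method <- match.arg(method)
  m <- tibble::as_tibble(measurements)
  cens <- which(m$below_loq)
  if (length(cens) == 0) return(m)
  switch(method,
    half_loq = { m$concentration[cens] <- m$loq[cens] / 2 },
    loq = { m$concentration[cens] <- m$loq[cens] },
    zero = { m$concentration[cens] <- 0 },
    drop = { m <- m[-cens, , drop = FALSE] }
  )
  m
}
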