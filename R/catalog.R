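#' Recognised concentration units
#'
#' The closed set of units in which regulatory levels for contaminants in
#' seafood are expressed: milligrams per kilogram wet weight (metals),
#' micrograms per kilogram wet weight (polycyclic aromatic hydrocarbons)
#' and picograms per gram wet weight (dioxins and dioxin-like PCBs).
#'
#' @return Character vector of the three unit labels.
#' @export
msfd_units <- function() {
  c("mg/kg w.w.", "\u00b5g/kg w.w.", "pg/g w.w.")
}

#' Built-in regulatory catalog
#'
#' The catalog of maximum contaminant levels in foodstuff categories used
#' for the Descriptor 9 assessment: cadmium, mercury and lead limits from
#' Regulation (EC) No 1881/2006, benzo(a)pyrene and the sum of four PAHs
#' (benzo(a)pyrene, benz(a)anthracene, benzo(b)fluoranthene, chrysene)
#' from Reg. 835/2011, and dioxins with dioxin-like PCBs from
#' Reg. 1259/2011. Each row is one regulatory category: a short code
#' (analyte plus the regulation's paragraph number), the foodstuff class,
#' the limit value and its unit, and the legislation reference.
#'
#' @return A tibble with columns `code`, `analyte`, `foodstuff`,
#'   `limit_value`, `limit_unit`, `legislation`; one row per regulatory
#'   category (17 rows).
#' @examples
#' msfd_catalog()
#' @export
msfd_catalog <- function() {
  mg <- "mg/kg w.w."
  ug <- "\u00b5g/kg w.w."
  pg <- "pg/g w.w."
  r1881 <- "Reg.1881/2006/CE"
  r835 <- "Reg.835/2011/CE"
  r1259 <- "Reg.1259/2011/CE"
  cat <- tibble::tribble(
    ~code, ~analyte, ~foodstuff, ~limit_value, ~limit_unit, ~legislation,
    "Cd 3.2.5", "Cd", "Muscle meat of fish", 0.05, mg, r1881,
    "Cd 3.2.6", "Cd", "Muscle meat of listened fish", 0.10, mg, r1881,
    "Cd 3.2.8", "Cd", "Crustaceans", 0.50, mg, r1881,
    "Cd 3.2.9", "Cd", "Bivalve molluscs", 1.0, mg, r1881,
    "Cd 3.2.10", "Cd", "Cephalopods", 1.0, mg, r1881,
    "Hg 3.3.1", "Hg", "Fishery products and muscle meat of fish", 0.50, mg, r1881,
    "Hg 3.3.2", "Hg", "Muscle meat of listened fish", 1.0, mg, r1881,
    "Pb 3.1.5", "Pb", "Muscle meat of fish", 0.3, mg, r1881,
    "Pb 3.1.6", "Pb", "Crustaceans", 0.50, mg, r1881,
    "Pb 3.1.7", "Pb", "Bivalve molluscs", 1.5, mg, r1881,
    "Pb 3.1.8", "Pb", "Cephalopods", 1.0, mg, r1881,
    "Dioxins 5.3", "Dioxins", "Muscle meat of fish and Bivalve molluscs", 3.5, pg, r1259,
    "Sum dioxins and dioxin like PCBs 5.3", "Sum dioxins and dl-PCBs",
      "Muscle meat of fish and Bivalve molluscs", 6.5, pg, r1259,
    "Benzo(a)pyrene 6.1.4", "Benzo(a)pyrene", "Muscle meat of fish", 2.0, ug, r1881,
    "Benzo(a)pyrene 6.1.5", "Benzo(a)pyrene", "Crustaceans and Cephalopods", 5.0, ug, r1881,
    "Benzo(a)pyrene 6.1.6", "Benzo(a)pyrene", "Bivalve molluscs", 5.0, ug, r835,
    "Sum PAH 6.1.6", "Sum of 4 PAHs", "Bivalve molluscs", 30.0, ug, r835
  )
  validate_catalog(cat)
}

#' Validate a regulatory catalog
#'
#' Checks the structural invariants every catalog must satisfy: the five
#' required columns are present, category codes are unique, limit values
#' are strictly positive and units belong to [msfd_units()].
#'
#' @param catalog A data frame of regulatory categories.
#' @return The catalog as a tibble, invisibly usable in a pipe; errors if
#'   any invariant is violated.
#' @export
validate_catalog <- function(catalog) {
  required <- c("code", "foodstuff", "limit_value", "limit_unit", "legislation")
  missing <- setdiff(required, names(catalog))
  check_that(length(missing) == 0,
             paste0("catalog is missing required column(s): ",
                    paste(missing, collapse = ", ")))
  dup <- catalog$code[duplicated(catalog$code)]
  check_that(length(dup) == 0,
             paste0("duplicate category code(s): ", paste(unique(dup), collapse = ", ")))
  bad_limit <- !is.finite(catalog$limit_value) | catalog$limit_value <= 0
  check_that(!any(bad_limit),
             paste0("non-positive limit_value for code(s): ",
                    paste(catalog$code[bad_limit], collapse = ", ")))
  bad_unit <- !catalog$limit_unit %in% msfd_units()
  check_that(!any(bad_unit),
             paste0("unknown limit_unit for code(s): ",
                    paste(catalog$code[bad_unit], collapse = ", ")))
  tibble::as_tibble(catalog)
}

#' Load a regulatory catalog
#'
#' @param source `"builtin"` for the packaged catalog, or the path of a
#'   delimited text file (comma or semicolon separated; decimal comma
#'   accepted via `decimal_mark`) with columns `code`, `foodstuff`,
#'   `limit_value`, `limit_unit`, `legislation` and optionally `analyte`.
#' @param decimal_mark Decimal separator used in the file, `"."` or `","`.
#' @return A validated catalog tibble. An empty table yields an empty
#'   catalog without error.
#' @examples
#' load_catalog("builtin")
#' @export
load_catalog <- function(source = "builtin", decimal_mark = ".") {
  if (identical(source, "builtin")) return(msfd_catalog())
  check_that(file.exists(source), paste0("catalog file not found: ", source))
  cat <- read_delimited(source, decimal_mark)
  validate_catalog(cat)
}

#' Write a catalog to delimited text
#'
#' Output always uses comma delimiters and decimal points, whatever
#' dialect the catalog was read from.
#'
#' @param catalog A catalog tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  readr::write_csv(catalog, path)
  invisible(path)
}

# Shared delimited-text reader: sniffs comma vs semicolon delimiters and
# honours a decimal-comma dialect (semicolon-delimited files only, since a
# comma cannot serve as both field and decimal separator). Numeric parsing
# goes through strtod, which is correctly rounded, so a write -> read
# round trip reproduces every double bit-for-bit.
read_delimited <- function(path, decimal_mark = ".") {
  header <- readLines(path, n = 1L)
  delim <- if (grepl(";", header, fixed = TRUE)) ";" else ","
  if (decimal_mark == "," && delim == ",") {
    abort("decimal_mark ',' requires a semicolon-delimited file")
  }
  out <- utils::read.table(
    path, header = TRUE, sep = delim, dec = decimal_mark, quote = "\"",
    comment.char = "", na.strings = c("NA", ""), check.names = FALSE,
    stringsAsFactors = FALSE, encoding = "UTF-8"
  )
  tibble::as_tibble(out)
}

#' Record counts of the Italian initial assessment
#'
#' The per-class record counts of the 2006-2012 Italian Descriptor 9
#' initial assessment, by Mediterranean subregion: metals (Hg, Cd, Pb),
#' PAHs, and halogenated organic compounds (dioxins and dioxin-like
#' PCBs). These published totals are packaged as reference input for
#' bookkeeping checks; the underlying ~15000 measurement records were
#' never deposited.
#'
#' @return A tibble with columns `subregion` (`"AS"` Adriatic Sea,
#'   `"WMS"` Western Mediterranean Sea, `"ISCMS"` Ionian Sea and Central
#'   Mediterranean Sea), `class` (`"Metals"`, `"PAHs"`, `"HOCs"`) and
#'   `n_records`.
#' @examples
#' dplyr::count(subregion_record_counts(), subregion, wt = n_records)
#' @export
subregion_record_counts <- function() {
  tibble::tribble(
    ~subregion, ~class, ~n_records,
    "AS", "Metals", 5801L,
    "AS", "PAHs", 1086L,
    "AS", "HOCs", 232L,
    "WMS", "Metals", 1344L,
    "WMS", "PAHs", 513L,
    "WMS", "HOCs", 43L,
    "ISCMS", "Metals", 5865L,
    "ISCMS", "PAHs", 92L,
    "ISCMS", "HOCs", 26L
  )
}

#' Published subregion totals and grid sizes
#'
#' Reported grand totals of assessed records per subregion and the number
#' of fishnet cells of each subregion's reference grid, for cross-checking
#' the per-class counts in [subregion_record_counts()].
#'
#' @return A tibble with columns `subregion`, `n_records_total`,
#'   `n_total_cells`.
#' @export
subregion_totals <- function() {
  tibble::tribble(
    ~subregion, ~n_records_total, ~n_total_cells,
    "AS", 7119L, 51L,
    "WMS", 1900L, 166L,
    "ISCMS", 5983L, 77L
  )
}
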