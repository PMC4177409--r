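test_that("well-formed measurement files read cleanly", {
  m <- make_measurements(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  got <- read_measurements(path)
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(measurement_problems(got)), 0L)
})

test_that("malformed rows are reported with row number and rule, not dropped silently", {
  m <- make_measurements(3)
  m$lat[2] <- 95
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  got <- read_measurements(path)
  expect_equal(nrow(got), 2L)
  pr <- measurement_problems(got)
  expect_equal(pr$row, 2L)
  expect_equal(pr$rule, "lat_range")

  m2 <- make_measurements(2)
  m2$category_code[2] <- "Xx 9.9.9"
  write_measurements(m2, path)
  got2 <- read_measurements(path)
  expect_equal(nrow(got2), 1L)
  expect_equal(measurement_problems(got2)$rule, "unresolved_category")
})

test_that("missing required columns are a hard error", {
  m <- make_measurements(2)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(m[setdiff(names(m), "concentration")], path)
  expect_error(read_measurements(path), "concentration")
})

test_that("decimal-comma semicolon dialect is accepted on input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("station_id", "lon", "lat", "year", "species", "tissue",
          "category_code", "concentration", "unit", "below_loq", "loq",
          sep = ";"),
    "S1;13,25;43,5;2010;mussel;soft tissue;Cd 3.2.9;0,42;mg/kg w.w.;FALSE;"
  ), path)
  got <- read_measurements(path, decimal_mark = ",")
  expect_equal(got$concentration, 0.42)
  expect_equal(got$lon, 13.25)
})

test_that("generated datasets round-trip through write/read losslessly", {
  scn <- scenario(n_stations = 25, seed = 9,
                  plan = dplyr::mutate(default_plan(), n_per_station = 1,
                                       years = list(2010:2011)))
  m <- gen_dataset(scn)
  expect_equal(nrow(m), 25 * 2 * nrow(default_plan()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_equal(nrow(back), nrow(m))
  expect_equal(nrow(measurement_problems(back)), 0L)
  # numeric fields to full precision
  expect_identical(back$concentration, m$concentration)
  expect_identical(back$lon, m$lon)
  expect_identical(back$lat, m$lat)
})

test_that("qc_filter removes by the documented predicates and conserves counts", {
  m <- make_measurements(10)
  m$lon[1] <- 30          # outside bbox
  m$unit[2] <- "pg/g w.w."  # unit mismatch
  m$below_loq[3] <- TRUE
  m$loq[3] <- 2 * 1.0     # loq above the Cd 3.2.9 limit -> uninformative
  kept <- qc_filter(m, bbox = c(10, 40, 20, 46))
  rep <- qc_report(kept)
  expect_equal(rep$n_input, 10L)
  expect_equal(rep$n_kept, 7L)
  expect_equal(rep$n_input, rep$n_kept + sum(rep$removed_by_rule))
  expect_equal(unname(rep$removed_by_rule[["bbox"]]), 1L)
  expect_equal(unname(rep$removed_by_rule[["unit_match"]]), 1L)
  expect_equal(unname(rep$removed_by_rule[["loq_informative"]]), 1L)

  all_ok <- qc_filter(make_measurements(5), bbox = c(10, 40, 20, 46))
  expect_equal(qc_report(all_ok)$n_kept, 5L)
  expect_true(all(qc_report(all_ok)$removed_by_rule == 0))
})

test_that("qc conservation holds for arbitrary generated inputs", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    m <- make_measurements(n,
      lon = runif(n, 5, 25), lat = runif(n, 35, 50),
      year = sample(2000:2015, n, replace = TRUE),
      concentration = runif(n, 0, 2))
    cens <- runif(n) < 0.3
    m$below_loq <- cens
    m$loq[cens] <- runif(sum(cens), 0, 3)
    kept <- qc_filter(m, bbox = c(10, 40, 20, 46))
    rep <- qc_report(kept)
    expect_equal(rep$n_input, rep$n_kept + sum(rep$removed_by_rule))
  }
})

test_that("below-LOQ substitution follows the selected convention", {
  m <- make_measurements(4, concentration = 1)
  m$below_loq[c(2, 4)] <- TRUE
  m$loq[c(2, 4)] <- 0.2
  expect_equal(substitute_loq(m, "half_loq")$concentration, c(1, 0.1, 1, 0.1))
  expect_equal(substitute_loq(m, "loq")$concentration, c(1, 0.2, 1, 0.2))
  expect_equal(substitute_loq(m, "zero")$concentration, c(1, 0, 1, 0))
  expect_equal(nrow(substitute_loq(m, "drop")), 2L)
})
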