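test_that("spatial coverage rounds half-up to one decimal", {
  expect_equal(spatial_coverage(0, 77), 0.0)
  expect_equal(spatial_coverage(51, 51), 100.0)
  # 42/51 x 100 = 82.352...: one assessed-cell count consistent with the
  # published mercury coverage of the Adriatic grid
  expect_equal(spatial_coverage(42, 51), 82.4)
  expect_error(spatial_coverage(5, 0), "at least 1")
  expect_error(spatial_coverage(52, 51), "<=")
})

test_that("exceedance frequency counts code-2 data", {
  ef <- exceedance_frequency(c(rep(1L, 15), 2L))
  expect_equal(ef$n_exceed, 1L)
  expect_equal(ef$pct_exceed, 6.3)
  expect_equal(exceedance_frequency(rep(1L, 9))$pct_exceed, 0.0)
  set.seed(12)
  for (i in 1:25) {
    codes <- sample(c(1L, 2L), sample(1:200, 1), replace = TRUE)
    ef <- exceedance_frequency(codes)
    expect_equal(ef$n_exceed, sum(codes == 2L))
    expect_equal(ef$pct_exceed, round_half_up(100 * mean(codes == 2L), 1))
  }
  expect_error(exceedance_frequency(integer(0)), "empty")
})

test_that("summary rows carry consistent percentages and counts", {
  m <- gen_dataset(scenario(n_stations = 15, seed = 31))
  a <- run_assessment(m, polygon = subregion_polygon("basin"))
  s <- a$summary
  with_data <- s[s$n_data > 0, ]
  expect_gt(nrow(with_data), 0)
  for (pair in list(c("pct_data_within", "pct_data_outside"),
                    c("pct_stations_within", "pct_stations_outside"),
                    c("pct_cells_within", "pct_cells_outside"))) {
    sums <- with_data[[pair[1]]] + with_data[[pair[2]]]
    expect_true(all(abs(sums - 100) <= 0.1))
  }
  expect_true(all(s$spatial_coverage_pct >= 0 | is.na(s$spatial_coverage_pct)))
  expect_true(all(s$n_cells_with_data <= s$n_total_cells))
  # categories with no data are emitted with NA percentages
  expect_true(any(is.na(s$pct_data_within)))
  expect_equal(nrow(s), nrow(msfd_catalog()))
})

test_that("one exceeding station of two in one cell forces the documented splits", {
  net_m <- make_measurements(2, concentration = c(0.4, 1.6),
                             lon = c(12.1, 12.2), lat = c(42.1, 42.2))
  coded <- code_measurements(net_m)
  st <- assess_stations(coded)
  net <- make_fishnet(c(12, 42, 13, 43), 1)
  grid <- clip_to_subregion(net, unit_square(12, 42, 1))
  cells <- assess_cells(st, grid$fishnet)
  s <- summarize_assessment(coded, st, cells, grid)
  row <- s[s$category_code == "Cd 3.2.9", ]
  expect_equal(row$pct_stations_within, 50.0)
  expect_equal(row$pct_cells_within, 0.0)   # tie in the single cell -> red
})

test_that("the fixed-width table mirrors the summary with '-' for no data", {
  m <- gen_dataset(scenario(n_stations = 6, seed = 41))
  a <- run_assessment(m, polygon = subregion_polygon("basin"))
  txt <- format_summary_table(a$summary)
  expect_true(any(grepl("% of spatial coverage", txt)))
  expect_true(any(grepl("% of cells within the limits", txt)))
  expect_true(any(grepl(" - ", txt)))   # empty categories render as "-"
  txt2 <- format_summary_table(a$summary, drop_empty = TRUE)
  expect_false(any(grepl(" - ", txt2)))
})

test_that("cell maps render green/red and round-trip through GeoJSON", {
  m <- gen_dataset(scenario(n_stations = 10, seed = 51))
  a <- run_assessment(m, polygon = subregion_polygon("basin"))
  one <- a$cells[a$cells$category_code == a$cells$category_code[1], ]
  path <- withr::local_tempfile(fileext = ".geojson")
  render_map(one, a$grid, path)
  back <- read_cell_map(path)
  expect_equal(nrow(back), nrow(one))
  merged <- dplyr::inner_join(back, one, by = "cell_id",
                              suffix = c(".map", ".src"))
  expect_equal(merged$code.map, merged$code.src)
  expect_true(all(merged$color[merged$code.map == 1L] == "green"))
  expect_true(all(merged$color[merged$code.map == 2L] == "red"))

  dangling <- dplyr::mutate(one, cell_id = paste0("x", cell_id))
  expect_error(render_map(dangling, a$grid, path), "absent")
})

test_that("plot functions return ggplot objects", {
  m <- gen_dataset(scenario(n_stations = 6, seed = 61))
  a <- run_assessment(m, polygon = subregion_polygon("basin"))
  one <- a$cells[a$cells$category_code == a$cells$category_code[1], ]
  p1 <- plot_cell_map(one, a$grid)
  p2 <- autoplot(a$grid)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})
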