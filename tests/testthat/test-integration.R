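test_that("datum coding treats the limit as not-exceeding", {
  expect_equal(code_datum(0.4, 0.50), 1L)   # Hg in fish muscle vs 0.50
  expect_equal(code_datum(0.50, 0.50), 1L)  # exactly at the limit
  expect_equal(code_datum(0.50 * 1.01, 0.50), 2L)
})

test_that("code_measurements joins limits and rejects unit mismatches", {
  m <- make_measurements(3, category_code = "Hg 3.3.1",
                         concentration = c(0.4, 0.5, 0.6))
  coded <- code_measurements(m)
  expect_equal(coded$code, c(1L, 1L, 2L))
  expect_equal(coded$limit_value, rep(0.5, 3))
  m$unit[2] <- "pg/g w.w."
  expect_error(code_measurements(m), "unit mismatch")
})

test_that("integrate_codes applies majority with precautionary ties", {
  expect_equal(integrate_codes(c(1L, 2L)), 2L)      # tie -> 2
  expect_equal(integrate_codes(c(1L, 1L, 2L)), 1L)  # majority
  expect_equal(integrate_codes(2L), 2L)
  expect_equal(integrate_codes(1L), 1L)             # idempotent singleton
  expect_error(integrate_codes(integer(0)), "empty")
  expect_error(integrate_codes(c(1L, 3L)), "1 or 2")
})

test_that("integrate_codes agrees with exhaustive count comparison to n = 12", {
  total <- 0L
  for (n in 1:12) {
    for (bits in 0:(2^n - 1)) {
      codes <- 1L + as.integer(intToBits(bits))[1:n]
      expect_identical(integrate_codes(codes), brute_integrate(codes))
      total <- total + 1L
    }
  }
  expect_equal(total, 8190L)
})

test_that("integration is permutation invariant and precautionary monotone", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:40, 1)
    codes <- sample(c(1L, 2L), n, replace = TRUE)
    expect_identical(integrate_codes(codes), integrate_codes(rev(sort(codes))))
    # flipping any 1 to 2 never moves the result from 2 to 1
    base <- integrate_codes(codes)
    ones <- which(codes == 1L)
    if (length(ones) > 0) {
      j <- sample(ones, 1)
      flipped <- codes; flipped[j] <- 2L
      if (base == 2L) expect_identical(integrate_codes(flipped), 2L)
    }
  }
})

test_that("station assessment integrates datum codes by the same rule", {
  m <- make_measurements(3, concentration = c(0.4, 0.5, 0.9))
  coded <- code_measurements(m)
  coded$station_id <- "S1"
  st <- assess_stations(coded)
  expect_equal(nrow(st), 1L)
  expect_equal(st$code, 1L)
  expect_equal(st$n_data, 3L)
  expect_equal(st$n_exceed, 0L)

  # 2 within + 2 above: the precautionary tie applies at station level
  m2 <- make_measurements(4, concentration = c(0.4, 0.5, 1.2, 1.4))
  coded2 <- code_measurements(m2)
  coded2$station_id <- "S1"
  expect_equal(assess_stations(coded2)$code, 2L)

  # 5 data, 1 above: majority keeps the station green
  m3 <- make_measurements(5, concentration = c(0.4, 0.4, 0.4, 0.4, 1.2))
  coded3 <- code_measurements(m3)
  coded3$station_id <- "S1"
  st3 <- assess_stations(coded3)
  expect_equal(st3$code, 1L)
  expect_equal(st3$n_exceed, 1L)
})

test_that("cell assessment pools stations and years by the majority/tie rule", {
  net <- make_fishnet(c(12, 42, 14, 44), 1)
  st <- tibble::tibble(
    station_id = c("A", "B", "C"),
    category_code = "Cd 3.2.9",
    lon = c(12.2, 12.4, 12.6), lat = c(42.3, 42.5, 42.7),
    years = "2010", code = c(1L, 1L, 2L), n_data = 1L, n_exceed = 0L
  )
  cells <- assess_cells(st, net)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$code, 1L)
  expect_equal(cells$n_stations_code1, 2L)

  # same station sampled in two years under single-year mode: two votes,
  # tie resolves red
  m <- make_measurements(2, concentration = c(0.4, 1.4),
                         year = c(2010L, 2011L))
  m$station_id <- "S1"
  coded <- code_measurements(m)
  st2 <- assess_stations(coded, mode = "single_year")
  expect_equal(nrow(st2), 2L)
  cells2 <- assess_cells(st2, net)
  expect_equal(cells2$code, 2L)

  # one station repeated across three years, all green
  m3 <- make_measurements(3, concentration = 0.4, year = c(2010L, 2011L, 2012L))
  m3$station_id <- "S1"
  st3 <- assess_stations(code_measurements(m3), mode = "single_year")
  expect_equal(assess_cells(st3, net)$code, 1L)
})

test_that("stations outside the net are excluded with a warning", {
  net <- make_fishnet(c(12, 42, 13, 43), 1)
  st <- tibble::tibble(
    station_id = c("A", "B"), category_code = "Cd 3.2.9",
    lon = c(12.5, 20), lat = c(42.5, 42.5),
    years = "2010", code = c(1L, 2L), n_data = 1L, n_exceed = 0L
  )
  expect_warning(cells <- assess_cells(st, net), "outside")
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$code, 1L)
})

test_that("end-to-end extremes force all-green and all-red cells", {
  plan0 <- dplyr::mutate(default_plan(), target_exceedance = 0,
                         n_per_station = 1, years = list(2010))
  m0 <- gen_dataset(scenario(n_stations = 12, seed = 21, plan = plan0))
  a0 <- run_assessment(m0, polygon = subregion_polygon("basin"))
  expect_true(all(a0$cells$code == 1L))

  plan1 <- dplyr::mutate(plan0, target_exceedance = 1)
  m1 <- gen_dataset(scenario(n_stations = 12, seed = 21, plan = plan1))
  a1 <- run_assessment(m1, polygon = subregion_polygon("basin"))
  expect_true(all(a1$cells$code == 2L))
})
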