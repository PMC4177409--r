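# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing is read from disk except files the tests write
# themselves.

# a minimal well-formed measurement tibble
make_measurements <- function(n = 3, category_code = "Cd 3.2.9",
                              concentration = 0.4, unit = "mg/kg w.w.",
                              lon = 13, lat = 43, year = 2010L,
                              station_id = sprintf("S%02d", seq_len(n))) {
  tibble::tibble(
    station_id = station_id,
    lon = lon, lat = lat, year = year,
    species = "Mytilus galloprovincialis", tissue = "soft tissue",
    category_code = category_code,
    concentration = concentration,
    unit = unit,
    below_loq = FALSE, loq = NA_real_
  )
}

# brute-force point-in-rectangle-bounds scan over all cells of a fishnet
brute_cell_of <- function(net, lon, lat) {
  d <- net$cell_size_deg
  hits <- matrix(NA_integer_, length(lon), 2)
  for (r in seq_len(net$n_rows) - 1L) {
    for (c in seq_len(net$n_cols) - 1L) {
      lo_x <- net$origin_lon + c * d; hi_x <- lo_x + d
      lo_y <- net$origin_lat + r * d; hi_y <- lo_y + d
      right_edge <- c == net$n_cols - 1L
      top_edge <- r == net$n_rows - 1L
      in_x <- lon >= lo_x & (lon < hi_x | (right_edge & lon == hi_x))
      in_y <- lat >= lo_y & (lat < hi_y | (top_edge & lat == hi_y))
      sel <- in_x & in_y & is.na(hits[, 1])
      hits[sel, ] <- rep(c(r, c), each = sum(sel))
    }
  }
  hits
}

# brute-force majority/tie integration by explicit count comparison
brute_integrate <- function(codes) {
  n1 <- sum(codes == 1L)
  n2 <- sum(codes == 2L)
  if (n1 > n2) 1L else 2L
}

# a unit square polygon ring
unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  cbind(lon = c(x0, x0 + side, x0 + side, x0),
        lat = c(y0, y0, y0 + side, y0 + side))
}
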