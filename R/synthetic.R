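#' Stylised subregion polygons
#'
#' Three packaged subregion boundary fixtures, generated in code so
#' tests never download coastlines: an elongated basin, a coast flanking
#' a peninsula, and a basin with an island (a two-ring polygon under the
#' even-odd rule). Coordinates are plausible Mediterranean
#' longitude/latitude but the shapes are synthetic.
#'
#' @param name One of `"basin"`, `"coast"`, `"islands"`.
#' @return A list of rings usable as a subregion polygon.
#' @examples
#' poly <- subregion_polygon("basin")
#' @export
subregion_polygon <- function(name = c("basin", "coast", "islands")) {
  name <- match.arg(name)
  ring <- switch(name,
    basin = cbind(
      lon = c(12.0, 13.5, 16.0, 18.5, 19.5, 18.0, 15.5, 13.0, 12.0),
      lat = c(44.8, 45.6, 44.9, 42.5, 40.5, 40.0, 41.5, 43.5, 44.8)
    ),
    coast = cbind(
      lon = c(8.0, 10.5, 12.5, 13.0, 11.5, 9.5, 7.5, 7.0, 8.0),
      lat = c(44.0, 43.5, 42.0, 40.0, 38.5, 39.5, 41.0, 43.0, 44.0)
    ),
    islands = cbind(
      lon = c(11.0, 15.5, 16.0, 14.0, 11.5, 10.5, 11.0),
      lat = c(39.5, 39.0, 37.0, 36.0, 36.5, 38.0, 39.5)
    )
  )
  rings <- list(ring)
  if (name == "islands") {
    rings <- c(rings, list(cbind(
      lon = c(12.8, 13.8, 13.6, 12.9, 12.8),
      lat = c(38.2, 38.1, 37.4, 37.5, 38.2)
    )))
  }
  rings
}

polygon_bbox <- function(polygon) {
  rings <- as_rings(polygon)
  lon <- unlist(purrr::map(rings, ~ .x[, 1]))
  lat <- unlist(purrr::map(rings, ~ .x[, 2]))
  c(min(lon), min(lat), max(lon), max(lat))
}

#' Generate monitoring stations inside a subregion
#'
#' Draws station locations uniformly inside the polygon by rejection
#' sampling from its bounding box. The optional coastal-bias mode pulls
#' each accepted point toward the nearest boundary vertex, mimicking the
#' concentration of monitoring effort in coastal fishing zones; the
#' default is uniform for statistical transparency.
#'
#' @param polygon Subregion polygon (ring or list of rings).
#' @param n Number of stations, `>= 1`.
#' @param seed Integer seed; identical seeds give identical stations.
#' @param coastal_bias Fraction in `[0, 1)` by which points are pulled
#'   toward the boundary (0 = uniform).
#' @return A tibble with `station_id` (`"ST0001"`, ...), `lon`, `lat`,
#'   all inside the polygon.
#' @export
gen_stations <- function(polygon, n, seed = 1L, coastal_bias = 0) {
  check_that(n >= 1, "need at least one station")
  rings <- as_rings(polygon)
  bbox <- polygon_bbox(rings)
  check_that(bbox[1] < bbox[3] && bbox[2] < bbox[4],
             "degenerate polygon: empty bounding box")
  old <- .Random.seed_exists(); on.exit(old$restore())
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    check_that(tries <= 1000L,
               "degenerate polygon: rejection sampling failed to hit it")
    m <- max(2L * (n - nrow(pts)), 64L)
    cand <- cbind(runif(m, bbox[1], bbox[3]), runif(m, bbox[2], bbox[4]))
    keep <- point_in_polygon(cand[, 1], cand[, 2], rings)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  if (coastal_bias > 0) {
    boundary <- do.call(rbind, rings)
    for (i in seq_len(n)) {
      d2 <- (boundary[, 1] - pts[i, 1])^2 + (boundary[, 2] - pts[i, 2])^2
      nearest <- boundary[which.min(d2), ]
      shifted <- pts[i, ] + coastal_bias * (nearest - pts[i, ])
      if (point_in_polygon(shifted[1], shifted[2], rings)) pts[i, ] <- shifted
    }
  }
  tibble::tibble(
    station_id = sprintf("ST%04d", seq_len(n)),
    lon = pts[, 1], lat = pts[, 2]
  )
}

#' Generate lognormal concentrations
#'
#' Draws from the lognormal concentration model the assessment assumes:
#' median `gm` and a natural-scale coefficient of variation `cv`, i.e.
#' log-scale parameters `meanlog = log(gm)`,
#' `sdlog = sqrt(log(1 + cv^2))`.
#'
#' @param n Number of draws.
#' @param gm Positive geometric mean (= median) of the distribution.
#' @param cv Positive natural-scale coefficient of variation.
#' @param seed Integer seed.
#' @return Positive numeric vector of length `n`.
#' @export
gen_concentrations <- function(n, gm, cv, seed = 1L) {
  check_that(gm > 0, "gm must be positive")
  check_that(cv > 0, "cv must be positive")
  old <- .Random.seed_exists(); on.exit(old$restore())
  set.seed(seed)
  rlnorm(n, meanlog = log(gm), sdlog = sigma_from_cv(cv))
}

#' Geometric mean attaining a target exceedance fraction
#'
#' Solves for the lognormal median at which a fraction `frac` of
#' concentrations exceeds the threshold `tl`:
#' `gm = tl * exp(-qnorm(1 - frac) * sigma)`. For `frac = 0` or `1`,
#' the median is placed six log-scale standard deviations below or
#' above the threshold so that exceedance is (numerically) never or
#' always.
#'
#' @param tl Positive threshold level.
#' @param frac Target exceedance fraction in `[0, 1]`.
#' @param cv Natural-scale coefficient of variation of the model.
#' @return The geometric mean, same unit as `tl`.
#' @export
gm_for_exceedance <- function(tl, frac, cv = 0.2) {
  check_that(all(tl > 0), "tl must be positive")
  check_that(all(frac >= 0 & frac <= 1), "frac must lie in [0, 1]")
  sigma <- sigma_from_cv(cv)
  z <- ifelse(frac <= 0, 6, ifelse(frac >= 1, -6, qnorm(1 - pmin(pmax(frac, 1e-12), 1 - 1e-12))))
  tl * exp(-z * sigma)
}

#' Define a synthetic monitoring scenario
#'
#' A scenario fixes everything the generator needs: the subregion
#' polygon, the station count, the per-category sampling plan and the
#' seed. Per-category plans give either a geometric mean `gm` directly
#' or a `target_exceedance` fraction from which the mean is solved via
#' [gm_for_exceedance()].
#'
#' @param polygon Subregion polygon (ring, list of rings, or a fixture
#'   name for [subregion_polygon()]).
#' @param n_stations Number of stations.
#' @param plan A tibble with one row per category: `category_code`,
#'   optional `gm`, optional `target_exceedance`, `cv` (default 0.2),
#'   `n_per_station` (default 2), and `years` (list-column or a single
#'   year range; default 2006:2012 sampled at each station).
#' @param seed Integer seed driving all randomness.
#' @param subregion Label carried into the measurement records.
#' @param catalog Regulatory catalog (for threshold lookups).
#' @return A `msfd9_scenario` list.
#' @export
scenario <- function(polygon = "basin", n_stations = 30,
                     plan = default_plan(), seed = 1L,
                     subregion = "synthetic", catalog = msfd_catalog()) {
  if (is.character(polygon)) polygon <- subregion_polygon(polygon)
  plan <- tibble::as_tibble(plan)
  if (!"cv" %in% names(plan)) plan$cv <- 0.2
  if (!"n_per_station" %in% names(plan)) plan$n_per_station <- 2L
  if (!"years" %in% names(plan)) plan$years <- list(2006:2012)
  if (!is.list(plan$years)) plan$years <- as.list(plan$years)
  if (!"gm" %in% names(plan)) plan$gm <- NA_real_
  if (!"target_exceedance" %in% names(plan)) plan$target_exceedance <- NA_real_
  check_that(all(plan$cv > 0), "plan cv must be positive")
  check_that(all(plan$n_per_station >= 1), "plan n_per_station must be >= 1")
  check_that(all(plan$category_code %in% catalog$code),
             "plan category codes must resolve in the catalog")
  idx <- match(plan$category_code, catalog$code)
  tl <- catalog$limit_value[idx]
  need <- is.na(plan$gm)
  bad <- need & (is.na(plan$target_exceedance) |
                   plan$target_exceedance < 0 | plan$target_exceedance > 1)
  check_that(!any(bad), "each plan row needs gm or a target_exceedance in [0, 1]")
  plan$gm[need] <- gm_for_exceedance(tl[need], plan$target_exceedance[need],
                                     plan$cv[need])
  plan$tl <- tl
  plan$unit <- catalog$limit_unit[idx]
  structure(
    list(polygon = as_rings(polygon), n_stations = n_stations, plan = plan,
         seed = as.integer(seed), subregion = subregion, catalog = catalog),
    class = "msfd9_scenario"
  )
}

#' Default per-category sampling plan
#'
#' A compact plan exercising the three contaminant classes the
#' assessment covers - two metal categories, one PAH and one dioxin
#' category - with a mostly compliant pattern (a 5 percent exceedance
#' target for mercury in fishery products, 2 percent for the rest),
#' echoing assessments in which most data sit within the limits.
#'
#' @return A plan tibble for [scenario()].
#' @export
default_plan <- function() {
  tibble::tribble(
    ~category_code, ~target_exceedance, ~species, ~tissue,
    "Hg 3.3.1", 0.05, "Mytilus galloprovincialis", "soft tissue",
    "Cd 3.2.9", 0.02, "Mytilus galloprovincialis", "soft tissue",
    "Benzo(a)pyrene 6.1.6", 0.02, "Mytilus galloprovincialis", "soft tissue",
    "Sum dioxins and dioxin like PCBs 5.3", 0.02, "Engraulis encrasicolus",
      "muscle"
  )
}

#' Generate a synthetic measurement dataset
#'
#' Produces the measurement table of a scenario (and optionally writes
#' it in the canonical measurement dialect together with a ground-truth
#' sidecar). Stations are scattered in the subregion; each station
#' contributes `n_per_station` records per category and year, with
#' lognormal concentrations. Identical scenarios and seeds give
#' byte-identical files.
#'
#' @param scn A [scenario()].
#' @param path Optional path of the measurement file to write.
#' @param sidecar_path Optional path of the ground-truth sidecar
#'   (key-value text recording true gm, cv and expected exceedance per
#'   category); default `paste0(path, ".truth")` when `path` is given.
#' @return The measurement tibble, with the ground-truth tibble in the
#'   `"truth"` attribute.
#' @examples
#' m <- gen_dataset(scenario(n_stations = 5, seed = 42))
#' attr(m, "truth")
#' @export
gen_dataset <- function(scn, path = NULL, sidecar_path = NULL) {
  check_that(inherits(scn, "msfd9_scenario"), "scn must be a scenario()")
  stations <- gen_stations(scn$polygon, scn$n_stations, seed = scn$seed)
  old <- .Random.seed_exists(); on.exit(old$restore())
  set.seed(scn$seed + 1L)
  sigma <- sigma_from_cv(scn$plan$cv)
  rows <- purrr::pmap(
    list(seq_len(nrow(scn$plan))),
    function(i) {
      p <- scn$plan[i, ]
      yrs <- p$years[[1]]
      grid <- tidyr::expand_grid(
        station_id = stations$station_id, year = as.integer(yrs),
        k = seq_len(p$n_per_station)
      )
      conc <- rlnorm(nrow(grid), meanlog = log(p$gm), sdlog = sigma[i])
      tibble::tibble(
        station_id = grid$station_id,
        lon = stations$lon[match(grid$station_id, stations$station_id)],
        lat = stations$lat[match(grid$station_id, stations$station_id)],
        year = grid$year,
        species = if ("species" %in% names(p)) p$species else
          "Mytilus galloprovincialis",
        tissue = if ("tissue" %in% names(p)) p$tissue else "soft tissue",
        category_code = p$category_code,
        concentration = conc,
        unit = p$unit,
        below_loq = FALSE,
        loq = NA_real_,
        subregion = scn$subregion
      )
    }
  )
  out <- purrr::list_rbind(rows)
  truth <- dplyr::transmute(
    scn$plan,
    category_code = .data$category_code,
    gm = .data$gm, cv = .data$cv, tl = .data$tl,
    expected_exceedance = 1 - stats::pnorm((log(.data$tl) - log(.data$gm)) /
                                             sigma_from_cv(.data$cv))
  )
  attr(out, "truth") <- truth
  if (!is.null(path)) {
    write_measurements(out, path)
    sidecar_path <- sidecar_path %||% paste0(path, ".truth")
    lines <- c(
      sprintf("seed=%d", scn$seed),
      sprintf("n_stations=%d", scn$n_stations),
      purrr::pmap_chr(truth, function(category_code, gm, cv, tl,
                                      expected_exceedance) {
        sprintf("category=%s\tgm=%.15g\tcv=%.15g\ttl=%.15g\texpected_exceedance=%.15g",
                category_code, gm, cv, tl, expected_exceedance)
      })
    )
    writeLines(lines, sidecar_path)
  }
  out
}
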