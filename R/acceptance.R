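#' Geometric mean
#'
#' @param values Strictly positive numeric vector (zeros must have been
#'   handled upstream by LOQ substitution).
#' @return `exp(mean(log(values)))`.
#' @examples
#' geometric_mean(c(1, 100))
#' @export
geometric_mean <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  check_that(length(bad) == 0,
             paste0("geometric mean requires positive values; offending index(es): ",
                    paste(head(bad, 5), collapse = ", ")))
  exp(mean(log(values)))
}

#' Empirical quantile
#'
#' Order-statistic quantile of the data. The default estimator linearly
#' interpolates the empirical distribution function (R quantile type 7);
#' the estimator is selectable because a compliance decision can hinge on
#' it when the empirical percentile sits near the regulatory level.
#'
#' @param values Non-empty numeric vector.
#' @param q Quantile fraction in (0, 1).
#' @param type Quantile estimator, one of R's types 1-9.
#' @return The estimated quantile (unnamed scalar).
#' @examples
#' empirical_quantile(1:10, 0.5)
#' @export
empirical_quantile <- function(values, q, type = 7) {
  check_that(length(values) >= 1, "empirical quantile of empty input")
  check_that(all(q > 0 & q < 1), "quantile fraction must lie in (0, 1)")
  unname(quantile(values, probs = q, type = type, names = FALSE))
}

#' Shapiro-Wilk test on log concentrations
#'
#' Tests the lognormality assumption underlying the acceptance range by
#' applying the Shapiro-Wilk normality test to the natural logarithms of
#' the data. The test is defined for 3 to 5000 observations; larger
#' samples are subsampled to 5000 with a fixed internal seed so the
#' reported p-value is reproducible.
#'
#' @param values Strictly positive numeric vector, `n >= 3`, not
#'   constant.
#' @param subsample_seed Seed used only for the over-5000 subsample.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_log <- function(values, subsample_seed = 20061L) {
  check_that(length(values) >= 3, "Shapiro test requires at least 3 values")
  check_that(all(values > 0), "Shapiro test on logs requires positive values")
  x <- log(values)
  check_that(diff(range(x)) > 0, "Shapiro test undefined for constant input")
  if (length(x) > 5000) {
    x <- local({
      old <- .Random.seed_exists()
      on.exit(old$restore())
      set.seed(subsample_seed)
      sample(x, 5000L)
    })
  }
  shapiro.test(x)$p.value
}

# save/restore .Random.seed so internal subsampling never perturbs the
# caller's random stream
.Random.seed_exists <- function() {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = env) else NULL
  list(restore = function() {
    if (had) assign(".Random.seed", saved, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
}

#' Log-scale standard deviation from a natural-scale CV
#'
#' For a lognormal variable with coefficient of variation `cv` on the
#' natural scale, the log-scale standard deviation is
#' `sqrt(log(1 + cv^2))`.
#'
#' @param cv Positive coefficient of variation.
#' @return Log-scale sigma.
#' @export
sigma_from_cv <- function(cv) {
  check_that(all(cv > 0), "cv must be positive")
  sqrt(log(1 + cv^2))
}

#' Fit the statistical range of acceptance
#'
#' Fits the lognormal acceptance model for one regulatory category: the
#' concentrations are assumed lognormal, anchored at the geometric mean
#' of the data, with a fixed 20 percent dispersion, and the regulatory
#' level plays the role of the distribution's 90th percentile. Two
#' readings of "sigma equal to 20 percent" are supported:
#'
#' * `"cv20"` (default): the fitted lognormal has median equal to the
#'   geometric mean and a natural-scale standard deviation of 20 percent
#'   of that median, i.e. `sigma = sqrt(log(1 + 0.2^2))`,
#'   `mu = log(gm)`. This reading is unit-free.
#' * `"literal_log"`: `mu = log(gm)`, `sigma = 0.2 * abs(mu)` - the
#'   literal log-scale reading, which depends on the measurement unit
#'   and degenerates when the geometric mean equals 1; retained for
#'   auditability.
#'
#' @param values Positive concentrations, `n >= 3`.
#' @param tl Regulatory threshold level in the same unit.
#' @param convention `"cv20"` or `"literal_log"`.
#' @param cv Natural-scale coefficient of variation under `"cv20"`
#'   (default 0.2, the environmental-data dispersion convention).
#' @param quantile_type Estimator for the empirical 90th percentile.
#' @return An object of class `acceptance_range`: a list with fields
#'   `n`, `gm`, `mu`, `sigma`, `tl`, `theoretical_p90` (the fitted
#'   lognormal's 90th percentile, `exp(mu + qnorm(0.9) * sigma)`),
#'   `empirical_p90`, `shapiro_p` and `convention`.
#' @examples
#' x <- rlnorm(50, meanlog = log(0.3), sdlog = sigma_from_cv(0.2))
#' fit <- fit_acceptance_range(x, tl = 0.5)
#' tidy(fit)
#' @export
fit_acceptance_range <- function(values, tl,
                                 convention = c("cv20", "literal_log"),
                                 cv = 0.2, quantile_type = 7) {
  convention <- match.arg(convention)
  check_that(length(values) >= 3, "acceptance range requires n >= 3")
  check_that(all(values > 0), "acceptance range requires positive values")
  check_that(is_scalar_number(tl) && tl > 0, "tl must be a positive scalar")
  gm <- geometric_mean(values)
  mu <- log(gm)
  sigma <- switch(convention,
    cv20 = sigma_from_cv(cv),
    literal_log = {
      s <- 0.2 * abs(mu)
      check_that(s > 0,
                 "literal_log convention degenerates when the geometric mean is 1")
      s
    }
  )
  structure(
    list(
      n = length(values),
      gm = gm,
      mu = mu,
      sigma = sigma,
      tl = tl,
      theoretical_p90 = exp(mu + qnorm(0.9) * sigma),
      empirical_p90 = empirical_quantile(values, 0.9, type = quantile_type),
      shapiro_p = shapiro_log(values),
      convention = convention
    ),
    class = "acceptance_range"
  )
}

#' @export
print.acceptance_range <- function(x, ...) {
  cat("Statistical range of acceptance (", x$convention, ")\n", sep = "")
  cat(sprintf("  n = %d, geometric mean = %.4g, mu = %.4g, sigma = %.4g\n",
              x$n, x$gm, x$mu, x$sigma))
  cat(sprintf("  TL = %.4g; theoretical p90 = %.4g; empirical p90 = %.4g\n",
              x$tl, x$theoretical_p90, x$empirical_p90))
  cat(sprintf("  Shapiro-Wilk on logs: p = %.3g\n", x$shapiro_p))
  invisible(x)
}

#' Tidy an acceptance-range fit
#'
#' @param x An `acceptance_range` object.
#' @param ... Unused.
#' @return A one-row tibble with the fitted quantities.
#' @method tidy acceptance_range
#' @export
tidy.acceptance_range <- function(x, ...) {
  tibble::tibble(
    n = x$n, gm = x$gm, mu = x$mu, sigma = x$sigma, tl = x$tl,
    theoretical_p90 = x$theoretical_p90, empirical_p90 = x$empirical_p90,
    shapiro_p = x$shapiro_p, convention = x$convention
  )
}

#' Glance at an acceptance-range fit
#'
#' @param x An `acceptance_range` object.
#' @param alpha Significance level for the lognormality gate.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `pass` (empirical 90th percentile does
#'   not exceed the threshold level), `margin` (`tl - empirical_p90`)
#'   and `normality_ok`.
#' @method glance acceptance_range
#' @export
glance.acceptance_range <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n = x$n,
    pass = x$empirical_p90 <= x$tl,
    margin = x$tl - x$empirical_p90,
    normality_ok = x$shapiro_p >= alpha
  )
}

#' Acceptance decision for one data set
#'
#' Decides compliance of a set of concentrations against a regulatory
#' threshold: the data pass when their empirical 90th percentile does
#' not exceed the threshold level (a tie passes, "must not exceed").
#' A failed lognormality check never flips the decision; it is reported
#' so the analyst can judge whether the acceptance model was apt.
#'
#' @inheritParams fit_acceptance_range
#' @param alpha Significance level for the lognormality gate
#'   (default 0.05).
#' @return A one-row tibble: `pass`, `margin` (`tl - empirical_p90`, in
#'   the category unit), `normality_ok`, plus the fitted quantities of
#'   [tidy.acceptance_range()].
#' @examples
#' assess_acceptance(c(0.1, 0.12, 0.15, 0.2), tl = 0.3)
#' @export
assess_acceptance <- function(values, tl,
                              convention = c("cv20", "literal_log"),
                              cv = 0.2, quantile_type = 7, alpha = 0.05) {
  fit <- fit_acceptance_range(values, tl, convention, cv, quantile_type)
  dplyr::bind_cols(
    glance(fit, alpha = alpha)[c("pass", "margin", "normality_ok")],
    tidy(fit)
  )
}

#' Per-category acceptance report
#'
#' Runs the acceptance-range fit for every regulatory category present
#' in a measurement table, after LOQ substitution. Categories with fewer
#' than 3 usable records are skipped with a warning (the fit is
#' undefined below n = 3).
#'
#' @param measurements Measurement tibble (QC-filtered).
#' @param catalog Regulatory catalog providing each category's
#'   threshold.
#' @param loq_method Censored-value convention for [substitute_loq()].
#' @inheritParams assess_acceptance
#' @return A tibble, one row per assessed category: `category_code`
#'   followed by the [assess_acceptance()] columns.
#' @export
assess_categories <- function(measurements, catalog = msfd_catalog(),
                              loq_method = "half_loq",
                              convention = c("cv20", "literal_log"),
                              cv = 0.2, quantile_type = 7, alpha = 0.05) {
  convention <- match.arg(convention)
  m <- substitute_loq(measurements, loq_method)
  m <- m[m$concentration > 0, , drop = FALSE]
  split(m, m$category_code) |>
    purrr::imap(function(grp, code) {
      if (nrow(grp) < 3) {
        warn(paste0("category ", code, " skipped: fewer than 3 usable records"))
        return(NULL)
      }
      tl <- catalog$limit_value[match(code, catalog$code)]
      dplyr::bind_cols(
        tibble::tibble(category_code = code),
        assess_acceptance(grp$concentration, tl, convention, cv,
                          quantile_type, alpha)
      )
    }) |>
    purrr::compact() |>
    purrr::list_rbind()
}

#' Write a per-category acceptance report
#'
#' @param report Tibble from [assess_categories()].
#' @param path Output path (comma delimited, decimal point).
#' @return `path`, invisibly.
#' @export
write_acceptance_report <- function(report, path) {
  cols <- c("category_code", "n", "gm", "mu", "sigma", "tl",
            "theoretical_p90", "empirical_p90", "shapiro_p", "pass")
  readr::write_csv(report[intersect(cols, names(report))], path)
  invisible(path)
}
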