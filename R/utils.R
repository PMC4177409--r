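#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; regulatory summary tables are
#' conventionally rounded half-up, so percentages such as 82.35 print as
#' 82.4.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(82.35, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# stopifnot-style check that raises a classed error usable by the CLI
check_that <- function(ok, msg, class = "msfd9_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
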