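#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.0005 -> 0.001 at
#' three digits), the convention used for the package's displayed suitability
#' values. Base [round()] rounds ties to even, which is the wrong convention
#' for reporting suitability indices quoted to a fixed number of decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, half away from zero.
#' @export
#' @examples
#' round_half_up(0.0625, 3)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# internal: stop with a consistent error class
sh_stop <- function(..., class = "stickyhab_error") {
  stop(errorCondition(paste0(...),
                      class = unique(c(class, "stickyhab_error"))))
}

# internal: check a numeric vector is finite
assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    sh_stop(what, " must be finite numeric (no NA/NaN/Inf)")
  }
  invisible(x)
}

# internal: check values lie in [0, 1]
assert_unit_interval <- function(x, what) {
  assert_finite(x, what)
  if (any(x < 0 | x > 1)) {
    sh_stop(what, " must lie in [0, 1]; got values outside that range")
  }
  invisible(x)
}

# internal: coerce and validate an ISO-8601 date scalar/vector
as_iso_date <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out)) sh_stop(what, " must be ISO-8601 dates (YYYY-MM-DD)")
  out
}
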