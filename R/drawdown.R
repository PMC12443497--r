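#' Daily water-level (stage) series
#'
#' Validated container for a daily reservoir stage record: strictly
#' consecutive calendar days with one finite level (m, gauge datum) each.
#' Gaps and duplicate dates are rejected rather than filled, so any
#' interpolation of missing days is an explicit caller decision.
#'
#' @param dates `Date` vector (or ISO-8601 strings), consecutive days.
#' @param levels numeric water levels in metres.
#' @return A `stage_series`: tibble with columns `date`, `level_m` and class
#'   `stage_series`.
#' @export
#' @examples
#' stage_series(as.Date("2019-04-01") + 0:5, c(170, 169.8, 169.7, 169.7, 169.5, 169.4))
stage_series <- function(dates, levels) {
  dates <- as_iso_date(dates)
  assert_finite(levels, "levels")
  if (length(dates) != length(levels) || length(dates) == 0L) {
    sh_stop("dates and levels must be equal-length, non-empty")
  }
  if (anyDuplicated(dates)) {
    sh_stop("duplicate dates: ",
            paste(unique(dates[duplicated(dates)]), collapse = ", "))
  }
  d <- diff(as.integer(dates))
  if (any(d != 1L)) {
    gap_after <- dates[which(d != 1L)]
    sh_stop("stage series has gaps or unordered dates after: ",
            paste(gap_after, collapse = ", "))
  }
  out <- tibble::tibble(date = dates, level_m = as.numeric(levels))
  class(out) <- c("stage_series", class(out))
  out
}

#' Cumulative water-level drop over a forward incubation window
#'
#' For each day t with a full forward window, the realized drop is
#' `max(0, level(t) - min(level(t+1), ..., level(t+window_days)))`: the
#' deepest excursion below the spawning-day level during the window.
#' Stranding is irreversible -- an egg exposed mid-window dies even if the
#' level recovers -- so the window minimum governs, not the endpoint level.
#' For monotone declines the two definitions coincide; the endpoint variant
#' is available via `method = "endpoint"` for sensitivity analysis. The drop
#' is attributed to the spawning day t (forward-looking window); the final
#' `window_days` days carry no value and are dropped.
#'
#' @param series a [stage_series()].
#' @param window_days length of the incubation window in days (default 5,
#'   spawning through attainment of free-swimming).
#' @param method `"window_min"` (default) or `"endpoint"`.
#' @return A `drawdown_series`: tibble with `date` and `drop_5d_m` (>= 0).
#' @export
five_day_drop <- function(series, window_days = 5L,
                          method = c("window_min", "endpoint")) {
  method <- match.arg(method)
  if (!inherits(series, "stage_series")) {
    sh_stop("series must be a stage_series")
  }
  window_days <- as.integer(window_days)
  if (window_days < 1L) sh_stop("window_days must be >= 1")
  n <- nrow(series)
  if (n <= window_days) {
    sh_stop("stage series too short: need more than ", window_days, " days")
  }
  lev <- series$level_m
  idx <- seq_len(n - window_days)
  drop <- vapply(idx, function(t) {
    fut <- lev[(t + 1L):(t + window_days)]
    ref <- if (method == "window_min") min(fut) else fut[window_days]
    max(0, lev[t] - ref)
  }, numeric(1))
  out <- tibble::tibble(date = series$date[idx], drop_5d_m = drop)
  class(out) <- c("drawdown_series", class(out))
  out
}

#' Water-level-fluctuation suitability (SI_L) time series
#'
#' Evaluates the drawdown suitability curve at each day's realized
#' `window_days` cumulative drop.
#'
#' @inheritParams five_day_drop
#' @param curve the drawdown `suitability_curve` (variable `"five_day_drop"`),
#'   e.g. from [make_drawdown_curve()].
#' @return A `drawdown_series` tibble with `date`, `drop_5d_m`, `si_l`.
#' @export
#' @examples
#' s <- stage_series(as.Date("2019-05-01") + 0:9, 170 - 0.1 * (0:9))
#' si_l_series(s, make_drawdown_curve(egg_depth_reference()))
si_l_series <- function(series, curve, window_days = 5L,
                        method = c("window_min", "endpoint")) {
  if (!inherits(curve, "suitability_curve")) {
    sh_stop("curve must be a suitability_curve")
  }
  if (!identical(curve$variable, "five_day_drop")) {
    sh_stop("curve variable mismatch: expected 'five_day_drop', got '",
            curve$variable, "'")
  }
  dd <- five_day_drop(series, window_days = window_days, method = method)
  dd$si_l <- evaluate_curve(curve, dd$drop_5d_m)
  dd
}

#' Mean SI_L over a date range
#'
#' Arithmetic mean of the suitability index over the defined (full-window)
#' days falling inside the range; trailing days without a full forward
#' window are never padded in.
#'
#' @param dd a `drawdown_series` with an `si_l` column ([si_l_series()]).
#' @param from,to range limits (`Date` or ISO strings), inclusive.
#' @return Scalar mean SI_L.
#' @export
period_mean_si_l <- function(dd, from = NULL, to = NULL) {
  if (!inherits(dd, "drawdown_series") || is.null(dd$si_l)) {
    sh_stop("dd must be a drawdown_series with an si_l column")
  }
  keep <- rep(TRUE, nrow(dd))
  if (!is.null(from)) keep <- keep & dd$date >= as_iso_date(from, "from")
  if (!is.null(to)) keep <- keep & dd$date <= as_iso_date(to, "to")
  if (!any(keep)) sh_stop("date range contains no defined SI_L days")
  mean(dd$si_l[keep])
}

#' Maximum sustainable constant daily decline
#'
#' The regulation threshold implied by a drawdown suitability curve: the
#' smallest cumulative drop at which suitability reaches 0, divided by the
#' incubation window length. A constant decline at this rate is the fastest
#' schedule whose window-total drop never exceeds the zero-suitability
#' point. For the reference egg-depth distribution (zero point 0.8 m) and a
#' 5-day window this is 0.16 m/day.
#'
#' @param curve a drawdown `suitability_curve` that reaches 0.
#' @param window_days incubation window length in days (default 5).
#' @return Decline rate in m/day.
#' @export
max_sustainable_daily_decline <- function(curve, window_days = 5L) {
  if (!inherits(curve, "suitability_curve")) {
    sh_stop("curve must be a suitability_curve")
  }
  window_days <- as.integer(window_days)
  if (window_days < 1L) sh_stop("window_days must be >= 1")
  zero <- which(curve$knots$s <= .Machine$double.eps)
  if (length(zero) == 0L) {
    sh_stop("curve never reaches suitability 0; no finite threshold exists")
  }
  curve$knots$x[zero[1L]] / window_days
}

#' Daily water-level change statistics over a range
#'
#' Regime descriptors from first differences of the stage record: the mean
#' daily change and the single largest daily drop (most negative
#' difference), both in m/day.
#'
#' @param series a [stage_series()].
#' @param from,to optional inclusive range limits.
#' @return List with `mean_daily_change` and `max_daily_drop`.
#' @export
decline_stats <- function(series, from = NULL, to = NULL) {
  if (!inherits(series, "stage_series")) {
    sh_stop("series must be a stage_series")
  }
  keep <- rep(TRUE, nrow(series))
  if (!is.null(from)) keep <- keep & series$date >= as_iso_date(from, "from")
  if (!is.null(to)) keep <- keep & series$date <= as_iso_date(to, "to")
  lev <- series$level_m[keep]
  if (length(lev) < 2L) sh_stop("need at least 2 days in range")
  d <- diff(lev)
  list(mean_daily_change = mean(d), max_daily_drop = min(d))
}
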