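#' Stage-regime specification for the synthetic gauge generator
#'
#' Describes a pre-impoundment ("pre_dam") or drawdown ("post_dam") daily
#' water-level regime at a single gauge. Post-dam daily changes are drawn
#' from a normal distribution around the month's mean decline, truncated at
#' the stated maximum daily drop (and at a small positive rise), reproducing
#' the printed mean/extreme statistics with no further distributional
#' assumption. Pre-dam levels are generally stable: a mean-reverting pulse
#' component models occasional rainfall rises that decay over the following
#' days, on top of small day-to-day noise.
#'
#' @param regime `"post_dam"` or `"pre_dam"`.
#' @param mean_change_by_month named numeric, mean daily level change (m/day)
#'   keyed by two-digit month. Post-dam defaults: April -0.22, May -0.32.
#' @param spread standard deviation of daily changes (m/day).
#' @param max_daily_drop most negative admissible daily change (m/day),
#'   post-dam default -0.61.
#' @param max_daily_rise largest admissible daily rise outside rainfall
#'   pulses (m/day).
#' @param pulse_prob daily probability of a rainfall pulse (pre-dam only).
#' @param pulse_magnitude length-2 range (m) of the pulse level rise.
#' @param pulse_decay fraction of the pulse component retained per day.
#' @param initial_level starting gauge level (m).
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(regime = c("post_dam", "pre_dam"),
                        mean_change_by_month = NULL,
                        spread = NULL,
                        max_daily_drop = -0.61,
                        max_daily_rise = 0.10,
                        pulse_prob = 0.20,
                        pulse_magnitude = c(0.4, 2.4),
                        pulse_decay = 0.7,
                        initial_level = 170) {
  regime <- match.arg(regime)
  if (is.null(mean_change_by_month)) {
    mean_change_by_month <- if (regime == "post_dam") {
      c("04" = -0.22, "05" = -0.32)
    } else {
      c("04" = 0, "05" = 0)
    }
  }
  if (is.null(names(mean_change_by_month)) ||
      any(!nzchar(names(mean_change_by_month)))) {
    sh_stop("mean_change_by_month must be named by two-digit month")
  }
  if (is.null(spread)) spread <- if (regime == "post_dam") 0.08 else 0.05
  assert_finite(spread, "spread")
  if (spread < 0) sh_stop("spread must be >= 0")
  if (max_daily_drop > 0) sh_stop("max_daily_drop must be <= 0")
  structure(
    list(regime = regime, mean_change_by_month = mean_change_by_month,
         spread = spread, max_daily_drop = max_daily_drop,
         max_daily_rise = max_daily_rise, pulse_prob = pulse_prob,
         pulse_magnitude = pulse_magnitude, pulse_decay = pulse_decay,
         initial_level = initial_level),
    class = "regime_spec"
  )
}

# truncated-normal draws by rejection; bounds are far in the tails for the
# default regimes so the acceptance rate is near 1
rtruncnorm_rej <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic daily stage series
#'
#' Draws a daily water-level record under a [regime_spec()]. Identical spec,
#' date range and seed give bit-identical output.
#'
#' @param spec a [regime_spec()].
#' @param start,end first and last dates (inclusive).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [stage_series()].
#' @export
#' @examples
#' spec <- regime_spec("post_dam")
#' gen_stage_series(spec, "2019-05-01", "2019-05-31", seed = 1)
gen_stage_series <- function(spec, start, end, seed = NULL) {
  if (!inherits(spec, "regime_spec")) sh_stop("spec must be a regime_spec")
  start <- as_iso_date(start, "start")
  end <- as_iso_date(end, "end")
  if (end < start) sh_stop("invalid range: end before start")
  dates <- seq(start, end, by = "day")
  gen <- function() {
    n <- length(dates)
    if (spec$regime == "post_dam") {
      mo <- format(dates, "%m")
      mu <- spec$mean_change_by_month[mo]
      if (anyNA(mu)) {
        sh_stop("no mean daily change specified for month(s): ",
                paste(unique(mo[is.na(mu)]), collapse = ", "))
      }
      ch <- vapply(seq_len(n - 1L), function(i) {
        rtruncnorm_rej(1L, mu[i], spec$spread,
                       spec$max_daily_drop, spec$max_daily_rise)
      }, numeric(1))
      levels <- spec$initial_level + c(0, cumsum(ch))
    } else {
      pulse <- numeric(n)
      for (i in seq_len(n)[-1L]) {
        pulse[i] <- spec$pulse_decay * pulse[i - 1L]
        if (stats::runif(1) < spec$pulse_prob) {
          pulse[i] <- pulse[i] +
            stats::runif(1, spec$pulse_magnitude[1L], spec$pulse_magnitude[2L])
        }
      }
      levels <- spec$initial_level + pulse + stats::rnorm(n, 0, spec$spread)
    }
    stage_series(dates, levels)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Hydraulic-field specification for the synthetic mesh generator
#'
#' Describes the statistical structure of a tributary backwater reach on an
#' unstructured mesh: depth increasing along the longitudinal axis toward
#' the receiving reservoir, a faster channel core (~0.3 m/s) with slow
#' (< 0.2 m/s) vegetated margins plus a few fast riffle reaches, and a
#' longitudinal temperature gradient from warmer unregulated upstream water
#' to cooler reservoir-backwater downstream. Defaults follow April--May
#' conditions in a drawdown-zone tributary: velocity 0--1.4 m/s, depth
#' 0--14.5 m, upstream mean 22.9 degC vs downstream 20.6 degC.
#'
#' @param n_cells number of mesh cells.
#' @param velocity_range,depth_range,temp_range admissible value ranges.
#' @param core_velocity typical channel-core velocity (m/s).
#' @param n_riffles number of fast reaches along the axis.
#' @param temp_upstream,temp_downstream longitudinal mean temperatures (degC).
#' @param temp_sd cell-level temperature noise (degC).
#' @param area_meanlog,area_sdlog log-normal cell-area parameters (m^2).
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_cells = 2000,
                       velocity_range = c(0, 1.4),
                       depth_range = c(0, 14.5),
                       temp_range = c(13.7, 29.2),
                       core_velocity = 0.3,
                       n_riffles = 3,
                       temp_upstream = 22.9,
                       temp_downstream = 20.6,
                       temp_sd = 1.2,
                       area_meanlog = log(100),
                       area_sdlog = 0.3) {
  if (n_cells < 1) sh_stop("n_cells must be >= 1")
  for (r in list(velocity_range, depth_range, temp_range)) {
    if (length(r) != 2L || r[1L] >= r[2L]) sh_stop("invalid range in spec")
  }
  structure(
    list(n_cells = as.integer(n_cells), velocity_range = velocity_range,
         depth_range = depth_range, temp_range = temp_range,
         core_velocity = core_velocity, n_riffles = as.integer(n_riffles),
         temp_upstream = temp_upstream, temp_downstream = temp_downstream,
         temp_sd = temp_sd, area_meanlog = area_meanlog,
         area_sdlog = area_sdlog),
    class = "field_spec"
  )
}

#' Generate a synthetic hydraulic field snapshot
#'
#' Scatters cells over a longitudinal axis `x` in \[0, 1\] (0 = upstream) and
#' a cross-channel coordinate `y` in \[-1, 1\] (0 = channel centre) and
#' assigns depth, velocity and temperature from the [field_spec()] gradients
#' plus noise, clamped to the declared ranges. Shallow slow vegetated-margin
#' cells in the jointly optimal window (velocity <= 0.2 m/s, depth
#' 0.4--0.6 m, 20--23 degC) occur at a realistically small rate, so
#' suitability maps are non-degenerate while high-HSI area stays a small
#' fraction of the reach.
#'
#' @param spec a [field_spec()].
#' @param date snapshot date.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [hydro_field()].
#' @export
gen_hydro_field <- function(spec = field_spec(), date = "2019-05-01",
                            seed = NULL) {
  if (!inherits(spec, "field_spec")) sh_stop("spec must be a field_spec")
  gen <- function() {
    n <- spec$n_cells
    x <- stats::runif(n)                 # longitudinal, 0 upstream
    y <- stats::runif(n, -1, 1)          # cross-channel, 0 centre
    clamp <- function(v, r) pmin(r[2L], pmax(r[1L], v))

    # concave longitudinal profile (x^0.7) and steep banks (|y|^4) keep the
    # shallow littoral fringe narrow: most of the reach is deep water with
    # very low spawning suitability, as in an impounded backwater
    depth <- spec$depth_range[2L] * x^0.7 * (1 - 0.9 * y^4) +
      stats::rnorm(n, 0, 0.15)
    depth <- clamp(depth, spec$depth_range)

    vel <- spec$core_velocity * (1 - y^2)
    if (spec$n_riffles > 0) {
      centres <- stats::runif(spec$n_riffles, 0.1, 0.9)
      amps <- stats::runif(spec$n_riffles, 0.5, 1.1)
      for (k in seq_len(spec$n_riffles)) {
        vel <- vel + amps[k] * exp(-((x - centres[k]) / 0.05)^2) * (1 - y^2)
      }
    }
    vel <- clamp(vel + stats::rnorm(n, 0, 0.03), spec$velocity_range)

    temp <- spec$temp_upstream -
      (spec$temp_upstream - spec$temp_downstream) * x +
      stats::rnorm(n, 0, spec$temp_sd)
    temp <- clamp(temp, spec$temp_range)

    area <- stats::rlnorm(n, spec$area_meanlog, spec$area_sdlog)
    hydro_field(
      tibble::tibble(cell_id = seq_len(n), area_m2 = area,
                     velocity_ms = vel, depth_m = depth, temp_c = temp),
      date = date
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Sample egg-deposition depths from a frequency table
#'
#' Draws depths bin-proportionally to the table counts with uniform
#' placement within each bin; the empirical distribution converges to the
#' piecewise-linear cumulative curve underlying [make_drawdown_curve()].
#'
#' @param n number of samples (>= 1).
#' @param table a [depth_frequency_table()]; default the packaged reference.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector of depths (m).
#' @export
#' @examples
#' d <- gen_egg_depths(1000, seed = 1)
#' range(d)  # within [0, 0.8]
gen_egg_depths <- function(n, table = egg_depth_reference(), seed = NULL) {
  if (!inherits(table, "depth_frequency_table")) {
    sh_stop("table must be a depth_frequency_table")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1L) sh_stop("n must be >= 1")
  gen <- function() {
    bin <- sample.int(length(table$counts), n, replace = TRUE,
                      prob = table$counts / table$total)
    stats::runif(n, table$lower[bin], table$upper[bin])
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic larvae-density series from an SI_L series
#'
#' Larvae captured on day t hatched from eggs spawned about `lag_days`
#' earlier, so density is proportional to `si_l(t - lag_days)` with
#' multiplicative log-normal observation noise (mean-one). Used to exercise
#' the lagged-correlation validation with known ground truth: at zero noise
#' the lagged Pearson correlation is exactly 1; the default noise is set so
#' recovered correlations fall in a moderate 0.4--0.8 band on typical
#' drawdown-season series.
#'
#' @param si_l a `drawdown_series` with `si_l` ([si_l_series()]).
#' @param lag_days spawning-to-capture lag (days).
#' @param noise log-scale standard deviation of the multiplicative noise.
#' @param scale density at SI_L = 1 (individuals per unit effort).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Tibble with `date` and `density` covering dates
#'   `si_l$date + lag_days`.
#' @export
gen_larvae_density <- function(si_l, lag_days = 5L, noise = 0.8,
                               scale = 100, seed = NULL) {
  if (!is.data.frame(si_l) || !all(c("date", "si_l") %in% names(si_l)) ||
      nrow(si_l) == 0L) {
    sh_stop("si_l must be a non-empty series with date and si_l columns")
  }
  lag_days <- as.integer(lag_days)
  if (nrow(si_l) <= lag_days) sh_stop("SI_L series shorter than the lag")
  if (noise < 0) sh_stop("noise must be >= 0")
  if (stats::sd(si_l$si_l) == 0) {
    warning("SI_L series is constant; lagged correlation with the ",
            "generated densities is undefined", call. = FALSE)
  }
  gen <- function() {
    mult <- if (noise == 0) rep(1, nrow(si_l)) else
      stats::rlnorm(nrow(si_l), meanlog = -noise^2 / 2, sdlog = noise)
    tibble::tibble(date = si_l$date + lag_days,
                   density = scale * si_l$si_l * mult)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
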