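#' Lagged Pearson correlation of larvae density against SI_L
#'
#' Larvae captured on day t hatched from eggs spawned about `lag_days`
#' earlier, so the water-level suitability record is shifted earlier by the
#' lag before correlating: density(t) is paired with si_l(t - lag_days).
#' The correlation and its two-sided t-test p-value come from
#' [stats::cor.test()] on the shifted pairing.
#'
#' @param si_l a series with `date` and `si_l` columns ([si_l_series()]).
#' @param density a series with `date` and `density` columns.
#' @param lag_days shift applied to the SI_L dates (days).
#' @return List with `r`, `n` (paired days) and `p`.
#' @export
lagged_pearson <- function(si_l, density, lag_days = 5L) {
  if (!is.data.frame(si_l) || !all(c("date", "si_l") %in% names(si_l))) {
    sh_stop("si_l must have date and si_l columns")
  }
  if (!is.data.frame(density) ||
      !all(c("date", "density") %in% names(density))) {
    sh_stop("density must have date and density columns")
  }
  lag_days <- as.integer(lag_days)
  shifted <- as_iso_date(si_l$date) + lag_days
  idx <- match(as_iso_date(density$date), shifted)
  ok <- !is.na(idx)
  x <- si_l$si_l[idx[ok]]
  y <- density$density[ok]
  if (length(x) < 3L) {
    sh_stop("fewer than 3 paired days after applying the lag")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    sh_stop("correlation undefined: an input series is constant over ",
            "the paired days")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Monte-Carlo egg-cohort survival under a realized drawdown
#'
#' Survival of a spawned cohort through the incubation window, under the
#' sharp stranding threshold that defines the drawdown suitability curve: an
#' egg deposited at depth z below the spawning-day surface survives the
#' window iff z exceeds the realized cumulative drop D at the spawning
#' date. Over samples from the deposition-depth distribution the surviving
#' fraction converges to `evaluate_curve(make_drawdown_curve(table), D)`,
#' making this the independent Monte-Carlo check of the SI_L construction.
#'
#' @param stage a [stage_series()] covering the window.
#' @param egg_depths sampled deposition depths (m), e.g. [gen_egg_depths()].
#' @param spawn_date the spawning day; its forward window must fit in
#'   `stage`.
#' @param window_days incubation window length (days).
#' @return Surviving fraction in `[0, 1]`.
#' @export
cohort_survival <- function(stage, egg_depths, spawn_date, window_days = 5L) {
  if (!inherits(stage, "stage_series")) sh_stop("stage must be a stage_series")
  assert_finite(egg_depths, "egg_depths")
  if (length(egg_depths) == 0L) sh_stop("no egg depths supplied")
  spawn_date <- as_iso_date(spawn_date, "spawn_date")
  dd <- five_day_drop(stage, window_days = window_days)
  i <- match(spawn_date, dd$date)
  if (is.na(i)) {
    sh_stop("the ", window_days, "-day window after ", format(spawn_date),
            " does not fit within the stage series")
  }
  mean(egg_depths > dd$drop_5d_m[i])
}
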