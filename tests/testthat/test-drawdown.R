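test_that("stage series rejects gaps, duplicates and non-finite levels", {
  d <- as.Date("2019-04-01")
  expect_s3_class(stage_series(d + 0:2, c(10, 10, 10)), "stage_series")
  expect_error(stage_series(d + c(0, 1, 3), c(10, 10, 10)), "gaps")
  expect_error(stage_series(d + c(0, 1, 1), c(10, 10, 10)), "duplicate")
  expect_error(stage_series(d + 0:1, c(10, NA)), "finite")
})

test_that("forward-window drop matches the brute-force oracle", {
  d <- as.Date("2019-04-01")
  # constant level: no drop
  s <- stage_series(d + 0:5, rep(10, 6))
  expect_equal(five_day_drop(s)$drop_5d_m, 0)
  # constant 0.16 m/day decline: window total 0.80
  s <- constant_decline(0.16, 6)
  expect_equal(five_day_drop(s)$drop_5d_m, 0.80)
  # mid-window minimum governs even though the level recovers
  lev <- c(10, 9.5, 9.8, 9.9, 10.2, 10.3)
  s <- stage_series(d + 0:5, lev)
  expect_equal(five_day_drop(s)$drop_5d_m, 0.5)
  expect_equal(five_day_drop(s)$drop_5d_m, brute_drop(lev, 1, 5))
  # random series against the oracle at every defined day
  withr::with_seed(7, {
    lev <- 170 + cumsum(rnorm(40, -0.1, 0.3))
    s <- stage_series(d + 0:39, lev)
    dd <- five_day_drop(s)
    expect_equal(dd$drop_5d_m,
                 vapply(1:35, function(t) brute_drop(lev, t, 5), numeric(1)))
    expect_true(all(dd$drop_5d_m >= 0))
  })
})

test_that("endpoint window variant uses the final-day level only", {
  d <- as.Date("2019-04-01")
  lev <- c(10, 9.5, 9.8, 9.9, 10.2, 10.3)
  s <- stage_series(d + 0:5, lev)
  expect_equal(five_day_drop(s, method = "endpoint")$drop_5d_m, 0)
  # monotone decline: both definitions coincide
  s2 <- constant_decline(0.1, 10)
  expect_equal(five_day_drop(s2)$drop_5d_m,
               five_day_drop(s2, method = "endpoint")$drop_5d_m)
})

test_that("short series and bad windows are explicit errors", {
  s <- constant_decline(0.1, 5)
  expect_error(five_day_drop(s), "too short")
  expect_error(five_day_drop(constant_decline(0.1, 10), window_days = 0),
               ">= 1")
})

test_that("SI_L series evaluates the drawdown curve at each day's drop", {
  curve <- make_drawdown_curve(ref_table())
  # constant level: SI_L identically 1
  s <- stage_series(as.Date("2019-04-01") + 0:9, rep(170, 10))
  expect_equal(si_l_series(s, curve)$si_l, rep(1, 5))
  # 0.32 m/day: 5-day drop 1.6 m, beyond the curve's zero point
  expect_equal(si_l_series(constant_decline(0.32, 12), curve)$si_l, rep(0, 7))
  # 0.1 m/day: drop 0.5 m, suitability from the cumulative egg fraction
  expect_equal(si_l_series(constant_decline(0.1, 12), curve)$si_l,
               rep(1 - 89 / 163, 7))
  # curve for the wrong variable is refused
  vel <- make_trapezoid_curve("velocity", c(0, 0.5), c(0, 0.2), "m/s")
  expect_error(si_l_series(s, vel), "mismatch")
})

test_that("constant decline obeys the closed form D = window * rate", {
  curve <- make_drawdown_curve(ref_table())
  for (r in seq(0, 0.3, by = 0.03)) {
    dd <- si_l_series(constant_decline(r, 15), curve)
    expect_equal(dd$drop_5d_m, rep(5 * r, 10))
    expect_equal(period_mean_si_l(dd), evaluate_curve(curve, 5 * r))
  }
})

test_that("period mean SI_L averages defined days and splits consistently", {
  curve <- make_drawdown_curve(ref_table())
  dd <- tibble::tibble(date = as.Date("2019-04-01") + 0:3,
                       drop_5d_m = 0, si_l = c(1, 0, 1, 0))
  class(dd) <- c("drawdown_series", class(dd))
  expect_equal(period_mean_si_l(dd), 0.5)
  expect_error(period_mean_si_l(dd, from = "2020-01-01"), "no defined")

  # splitting a range and recombining with day-count weights is invariant
  withr::with_seed(42, {
    s <- gen_stage_series(regime_spec("pre_dam"), "2019-04-01", "2019-05-31")
    sl <- si_l_series(s, curve)
    whole <- period_mean_si_l(sl, "2019-04-01", "2019-05-26")
    a <- sl[sl$date <= as.Date("2019-04-20"), ]
    b <- sl[sl$date > as.Date("2019-04-20"), ]
    split_mean <- (sum(a$si_l) + sum(b$si_l)) / (nrow(a) + nrow(b))
    expect_equal(whole, split_mean)
  })
})

test_that("maximum sustainable decline is the zero point over the window", {
  curve <- make_drawdown_curve(ref_table())
  expect_equal(max_sustainable_daily_decline(curve), 0.16)
  expect_equal(max_sustainable_daily_decline(curve, window_days = 4), 0.2)
  # synthetic curve reaching zero at 1.0 m
  tab <- depth_frequency_table(c(0, 0.5), c(0.5, 1.0), c(3, 7))
  expect_equal(max_sustainable_daily_decline(make_drawdown_curve(tab)), 0.2)
  # curve that never reaches zero has no finite threshold
  flat <- make_trapezoid_curve("five_day_drop", c(0, 1), c(0, 1), "m")
  expect_error(max_sustainable_daily_decline(flat), "never reaches")
})

test_that("decline statistics report mean change and worst daily drop", {
  d <- as.Date("2019-05-01")
  s <- stage_series(d + 0:2, c(10, 9.8, 9.6))
  st <- decline_stats(s)
  expect_equal(st$mean_daily_change, -0.2)
  expect_equal(st$max_daily_drop, -0.2)
  s2 <- stage_series(d + 0:2, c(10, 9.9, 9.3))
  st2 <- decline_stats(s2)
  expect_equal(st2$mean_daily_change, -0.35)
  expect_equal(st2$max_daily_drop, -0.6)
  expect_error(decline_stats(stage_series(d, 10)), "at least 2")
})
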