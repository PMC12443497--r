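test_that("HSI combination gives the geometric mean or plain product", {
  expect_equal(spawning_hsi(1, 1, 1), 1)
  expect_equal(spawning_hsi(0.5, 0.5, 0.5), 0.5)
  expect_equal(spawning_hsi(0.5, 0.5, 0.5, mode = "product"), 0.125)
  expect_equal(hatching_hsi(1, 1, 1, 0), 0)
  expect_equal(round_half_up(hatching_hsi(1, 1, 1, 0.994), 4), 0.9985)
  expect_equal(hatching_hsi(1, 1, 1, 0.994), 0.994^(1 / 4))
  # SI_L = 1 is the identity in product mode
  expect_equal(hatching_hsi(0.5, 0.5, 0.5, 1, mode = "product"),
               spawning_hsi(0.5, 0.5, 0.5, mode = "product"))
  expect_error(spawning_hsi(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(hatching_hsi(0.5, 0.5, 0.5, -0.1), "\\[0, 1\\]")
})

test_that("any zero factor annihilates the HSI in both modes", {
  withr::with_seed(31, {
    for (i in 1:200) {
      fs <- runif(3)
      fs[sample.int(3, 1)] <- 0
      fh <- runif(4)
      fh[sample.int(4, 1)] <- 0
      expect_identical(spawning_hsi(fs[1], fs[2], fs[3]), 0)
      expect_identical(spawning_hsi(fs[1], fs[2], fs[3], mode = "product"), 0)
      expect_identical(hatching_hsi(fh[1], fh[2], fh[3], fh[4]), 0)
      expect_identical(hatching_hsi(fh[1], fh[2], fh[3], fh[4],
                                    mode = "product"), 0)
    }
  })
})

test_that("HSI is non-decreasing in every factor", {
  withr::with_seed(32, {
    for (mode in c("geometric_mean", "product")) {
      f <- matrix(runif(400), ncol = 4)
      for (j in 1:4) {
        g <- f
        g[, j] <- pmin(1, f[, j] + runif(100, 0, 1 - f[, j]))
        expect_true(all(
          hatching_hsi(g[, 1], g[, 2], g[, 3], g[, 4], mode = mode) >=
            hatching_hsi(f[, 1], f[, 2], f[, 3], f[, 4], mode = mode) - 1e-12
        ))
      }
    }
  })
})

test_that("classification uses half-open bins with a closed top", {
  expect_equal(as.character(classify_hsi(0.15)), "very_low")
  expect_equal(as.character(classify_hsi(0.2)), "low")
  expect_equal(as.character(classify_hsi(c(0, 0.4, 0.6, 0.8, 1.0))),
               c("very_low", "medium", "high", "very_high", "very_high"))
  expect_error(classify_hsi(1.1), "\\[0, 1\\]")
  expect_error(classify_hsi(-0.01), "\\[0, 1\\]")
})

test_that("weighted usable area equals the brute-force sum", {
  expect_equal(weighted_usable_area(c(10, 20), c(0.5, 0.25)), 10)
  expect_equal(weighted_usable_area(c(10, 20), c(0, 0)), 0)
  withr::with_seed(33, {
    area <- runif(100, 1, 500)
    hsi <- runif(100)
    acc <- 0
    for (i in seq_along(area)) acc <- acc + area[i] * hsi[i]
    expect_equal(weighted_usable_area(area, hsi), acc)
  })
  expect_error(weighted_usable_area(numeric(0), numeric(0)), "empty")
  expect_error(weighted_usable_area(c(-1, 2), c(0.5, 0.5)), "positive")
})

test_that("per-cell suitabilities follow the curves and shared SI_L", {
  cells <- tibble::tibble(
    cell_id = 1:3, area_m2 = c(10, 10, 10),
    velocity_ms = c(0.1, 0.6, 0.35),
    depth_m = c(0.5, 0.5, 0.3),
    temp_c = c(21, 21, 17.5)
  )
  f <- hydro_field(cells, "2019-05-01")
  su <- cell_suitabilities(f, si_l = 1)
  expect_equal(su$si_v, c(1, 0, 0.5))
  expect_equal(su$si_h, c(1, 1, 0.5))
  expect_equal(su$si_t, c(1, 1, 0.5))
  expect_equal(su$hsi_spawn, c(1, 0, 0.5))
  expect_equal(su$hsi_hatch[1], 1)
  expect_error(cell_suitabilities(f, si_l = 1.5), "\\[0, 1\\]")
  expect_error(cell_suitabilities(f, curves = list(velocity = 1)), "named list")
})

test_that("dry cells get zero HSI through the depth curve", {
  cells <- tibble::tibble(cell_id = 1L, area_m2 = 5,
                          velocity_ms = 0.1, depth_m = 0, temp_c = 21)
  su <- cell_suitabilities(hydro_field(cells, "2019-05-01"), si_l = 1)
  expect_identical(su$hsi_spawn, 0)
  expect_identical(su$hsi_hatch, 0)
})

test_that("class-area fractions sum to 1 and respond to SI_L", {
  withr::with_seed(34, {
    f <- gen_hydro_field(field_spec(n_cells = 500), "2019-05-01")
    for (si_l in c(0.2, 0.7, 1)) {
      su <- cell_suitabilities(f, si_l = si_l)
      tab <- class_area_table(su)
      expect_equal(sum(tab$spawn_fraction), 1)
      expect_equal(sum(tab$hatch_fraction), 1)
    }
    # a strong drawdown shifts hatching area out of the top classes
    su <- cell_suitabilities(f, si_l = 0.2)
    tab <- class_area_table(su)
    hi <- tab$class %in% c("high", "very_high")
    expect_lt(sum(tab$hatch_fraction[hi]), sum(tab$spawn_fraction[hi]))
  })
})

test_that("product mode orders hatching WUA at or below spawning WUA", {
  withr::with_seed(35, {
    f <- gen_hydro_field(field_spec(n_cells = 500), "2019-05-01")
    for (si_l in c(0, 0.3, 0.8, 1)) {
      su <- cell_suitabilities(f, si_l = si_l, mode = "product")
      wua_s <- weighted_usable_area(su$area_m2, su$hsi_spawn)
      wua_h <- weighted_usable_area(su$area_m2, su$hsi_hatch)
      expect_lte(wua_h, wua_s + 1e-9)
      if (si_l == 1) expect_equal(wua_h, wua_s)
    }
    # hatching WUA is non-decreasing in SI_L with all else fixed
    for (mode in c("geometric_mean", "product")) {
      wua <- vapply(seq(0, 1, by = 0.1), function(s) {
        su <- cell_suitabilities(f, si_l = s, mode = mode)
        weighted_usable_area(su$area_m2, su$hsi_hatch)
      }, numeric(1))
      expect_true(all(diff(wua) >= -1e-9))
    }
  })
})

test_that("habitat summary aggregates WUA and class areas per date", {
  withr::with_seed(36, {
    f <- gen_hydro_field(field_spec(n_cells = 300), "2019-05-01")
    si_l <- tibble::tibble(date = as.Date("2019-05-01") + 0:2,
                           si_l = c(1, 0.5, 0))
    sm <- habitat_summary(f, si_l, mode = "product")
    expect_equal(nrow(sm), 3L)
    # SI_L = 1 in product mode: hatching equals spawning, reduction 0
    expect_equal(sm$wua_hatch_m2[1], sm$wua_spawn_m2[1])
    expect_equal(sm$wua_reduction_pct[1], 0)
    # SI_L = 0: no hatching habitat at all
    expect_equal(sm$wua_hatch_m2[3], 0)
    expect_equal(sm$wua_reduction_pct[3], 100)
    expect_true(all(sm$mode == "product"))
    fr <- as.matrix(sm[, paste0("spawn_", c("very_low", "low", "medium",
                                            "high", "very_high"))])
    expect_equal(unname(rowSums(fr)), rep(1, 3))
  })
})

test_that("habitat summary refuses misaligned field dates", {
  withr::with_seed(37, {
    f1 <- gen_hydro_field(field_spec(n_cells = 50), "2019-05-01")
    si_l <- tibble::tibble(date = as.Date("2019-05-01") + 0:1, si_l = c(1, 1))
    expect_error(habitat_summary(list(f1), si_l), "no hydro_field for date")
    f2 <- gen_hydro_field(field_spec(n_cells = 50), "2019-05-02")
    sm <- habitat_summary(list(f1, f2), si_l)
    expect_equal(nrow(sm), 2L)
  })
})
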