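#' Per-cell hydraulic field snapshot
#'
#' One date's two-dimensional hydraulic state on the computational mesh:
#' per-cell area (m^2), depth-averaged velocity (m/s), water depth (m) and
#' temperature (degC). Cell ids must be unique, areas strictly positive,
#' velocity and depth non-negative.
#'
#' @param cells data frame with columns `cell_id`, `area_m2`, `velocity_ms`,
#'   `depth_m`, `temp_c`.
#' @param date the snapshot date.
#' @return A `hydro_field` object.
#' @export
hydro_field <- function(cells, date) {
  cells <- tibble::as_tibble(cells)
  need <- c("cell_id", "area_m2", "velocity_ms", "depth_m", "temp_c")
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    sh_stop("field is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(cells) == 0L) sh_stop("field has no cells")
  if (anyDuplicated(cells$cell_id)) sh_stop("cell ids must be unique")
  for (col in c("area_m2", "velocity_ms", "depth_m", "temp_c")) {
    assert_finite(cells[[col]], col)
  }
  bad <- cells$cell_id[cells$area_m2 <= 0]
  if (length(bad)) {
    sh_stop("non-positive area for cell(s): ",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (any(cells$velocity_ms < 0) || any(cells$depth_m < 0)) {
    sh_stop("velocity and depth must be non-negative")
  }
  structure(list(date = as_iso_date(date), cells = cells[need]),
            class = "hydro_field")
}

#' @export
print.hydro_field <- function(x, ...) {
  cat("<hydro_field> ", format(x$date), ", ", nrow(x$cells), " cells, total ",
      format(sum(x$cells$area_m2), big.mark = ","), " m^2\n", sep = "")
  invisible(x)
}

check_hsi_mode <- function(mode) {
  match.arg(mode, c("geometric_mean", "product"))
}

combine_si <- function(factors, mode) {
  prod <- Reduce(`*`, factors)
  if (mode == "geometric_mean") prod^(1 / length(factors)) else prod
}

#' Spawning habitat suitability index
#'
#' Combines the velocity, depth and temperature suitabilities of a cell into
#' the spawning-phase HSI. The default combination is the geometric mean of
#' the three factors; `mode = "product"` uses the plain product instead (see
#' the methods vignette for why both are offered). In either mode a zero in
#' any factor annihilates the HSI.
#'
#' @param si_v,si_h,si_t suitabilities in `[0, 1]` (vectorized).
#' @param mode `"geometric_mean"` (default) or `"product"`.
#' @return HSI values in `[0, 1]`.
#' @export
#' @examples
#' spawning_hsi(0.5, 0.5, 0.5)            # geometric mean -> 0.5
#' spawning_hsi(0.5, 0.5, 0.5, "product") # -> 0.125
spawning_hsi <- function(si_v, si_h, si_t,
                         mode = c("geometric_mean", "product")) {
  mode <- check_hsi_mode(mode)
  assert_unit_interval(si_v, "si_v")
  assert_unit_interval(si_h, "si_h")
  assert_unit_interval(si_t, "si_t")
  combine_si(list(si_v, si_h, si_t), mode)
}

#' Hatching habitat suitability index
#'
#' The hatching-phase HSI adds the water-level-fluctuation suitability SI_L
#' to the three hydraulic factors: geometric-mean mode takes the fourth root
#' of the product, product mode the plain product. Use the same mode as
#' [spawning_hsi()] within a run.
#'
#' @inheritParams spawning_hsi
#' @param si_l water-level-fluctuation suitability in `[0, 1]`.
#' @return HSI values in `[0, 1]`.
#' @export
hatching_hsi <- function(si_v, si_h, si_t, si_l,
                         mode = c("geometric_mean", "product")) {
  mode <- check_hsi_mode(mode)
  assert_unit_interval(si_v, "si_v")
  assert_unit_interval(si_h, "si_h")
  assert_unit_interval(si_t, "si_t")
  assert_unit_interval(si_l, "si_l")
  combine_si(list(si_v, si_h, si_t, si_l), mode)
}

HSI_CLASSES <- c("very_low", "low", "medium", "high", "very_high")
HSI_BREAKS <- c(0, 0.2, 0.4, 0.6, 0.8, 1)

#' Classify HSI values into the five suitability categories
#'
#' Bins: very_low \[0, 0.2), low \[0.2, 0.4), medium \[0.4, 0.6),
#' high \[0.6, 0.8), very_high \[0.8, 1\]. Boundaries go to the upper class
#' (0.2 is `low`); 1.0 is `very_high`.
#'
#' @param hsi numeric vector in `[0, 1]`.
#' @return Factor with levels `very_low` < `low` < `medium` < `high` <
#'   `very_high`.
#' @export
classify_hsi <- function(hsi) {
  assert_unit_interval(hsi, "hsi")
  cut(hsi, breaks = HSI_BREAKS, labels = HSI_CLASSES,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Per-cell suitabilities and HSI for one field snapshot
#'
#' Evaluates the three hydraulic suitability curves at each cell's velocity,
#' depth and temperature, applies the (spatially uniform) SI_L of the date,
#' and returns per-cell spawning and hatching HSI with class labels. SI_L is
#' a single gauge-derived scalar per date, matching a one-station stage
#' record; dry cells (depth 0) get si_h = 0 through the depth curve and
#' hence HSI 0 with no special-casing.
#'
#' @param field a [hydro_field()].
#' @param curves named list with `velocity`, `depth`, `temperature`
#'   suitability curves (e.g. [default_suitability_curves()]).
#' @param si_l scalar SI_L in `[0, 1]` for the field's date.
#' @param mode HSI combination mode, see [spawning_hsi()].
#' @return Tibble with `cell_id`, `area_m2`, `si_v`, `si_h`, `si_t`, `si_l`,
#'   `hsi_spawn`, `hsi_hatch`, `class_spawn`, `class_hatch`.
#' @export
cell_suitabilities <- function(field, curves = default_suitability_curves(),
                               si_l = 1,
                               mode = c("geometric_mean", "product")) {
  mode <- check_hsi_mode(mode)
  if (!inherits(field, "hydro_field")) sh_stop("field must be a hydro_field")
  need <- c("velocity", "depth", "temperature")
  if (!all(need %in% names(curves)) ||
      !all(vapply(curves[need], inherits, logical(1), "suitability_curve"))) {
    sh_stop("curves must be a named list of suitability_curves with ",
            "elements velocity, depth, temperature")
  }
  if (length(si_l) != 1L) sh_stop("si_l must be a scalar")
  assert_unit_interval(si_l, "si_l")
  cells <- field$cells
  si_v <- evaluate_curve(curves$velocity, cells$velocity_ms)
  si_h <- evaluate_curve(curves$depth, cells$depth_m)
  si_t <- evaluate_curve(curves$temperature, cells$temp_c)
  tibble::tibble(
    cell_id = cells$cell_id,
    area_m2 = cells$area_m2,
    si_v = si_v, si_h = si_h, si_t = si_t, si_l = si_l,
    hsi_spawn = spawning_hsi(si_v, si_h, si_t, mode),
    hsi_hatch = hatching_hsi(si_v, si_h, si_t, si_l, mode),
    class_spawn = classify_hsi(spawning_hsi(si_v, si_h, si_t, mode)),
    class_hatch = classify_hsi(hatching_hsi(si_v, si_h, si_t, si_l, mode))
  )
}

#' Weighted usable area
#'
#' `WUA = sum(A_i * HSI_i)` over all cells: the HSI-weighted sum of cell
#' areas, an area-equivalent of habitat quality in m^2.
#'
#' @param area cell areas in m^2.
#' @param hsi per-cell HSI in `[0, 1]`.
#' @return WUA in m^2.
#' @export
#' @examples
#' weighted_usable_area(c(10, 20), c(0.5, 0.25))  # 10 m^2
weighted_usable_area <- function(area, hsi) {
  assert_finite(area, "area")
  assert_unit_interval(hsi, "hsi")
  if (length(area) == 0L) sh_stop("empty cell collection")
  if (length(area) != length(hsi)) sh_stop("area and hsi lengths differ")
  if (any(area <= 0)) sh_stop("areas must be positive")
  sum(area * hsi)
}

#' Suitability-class area fractions for spawning and hatching
#'
#' Area share of each suitability class per reproductive stage, plus the
#' relative change from spawning to hatching,
#' `100 * (hatch - spawn) / spawn` per class (NA when the spawning share is
#' 0). Fractions within a stage sum to 1.
#'
#' @param suits per-cell suitability table from [cell_suitabilities()].
#' @return Tibble with `class`, `spawn_fraction`, `hatch_fraction`,
#'   `change_pct`.
#' @export
class_area_table <- function(suits) {
  need <- c("area_m2", "class_spawn", "class_hatch")
  if (!is.data.frame(suits) || !all(need %in% names(suits)) ||
      nrow(suits) == 0L) {
    sh_stop("suits must be a non-empty cell_suitabilities() table")
  }
  total <- sum(suits$area_m2)
  frac <- function(cls) {
    vapply(HSI_CLASSES,
           function(k) sum(suits$area_m2[cls == k]) / total, numeric(1))
  }
  sp <- frac(suits$class_spawn)
  ha <- frac(suits$class_hatch)
  tibble::tibble(
    class = factor(HSI_CLASSES, levels = HSI_CLASSES, ordered = TRUE),
    spawn_fraction = sp,
    hatch_fraction = ha,
    change_pct = ifelse(sp > 0, 100 * (ha - sp) / sp, NA_real_)
  )
}

#' Habitat summary time series
#'
#' Runs the per-cell suitability model for each date in an SI_L series and
#' aggregates WUA and class-area fractions for both reproductive stages.
#'
#' @param fields a single [hydro_field()] applied to every date, or a list of
#'   `hydro_field`s whose dates must cover the SI_L dates exactly.
#' @param si_l a `drawdown_series` with `si_l` ([si_l_series()]) or a data
#'   frame with `date` and `si_l` columns.
#' @param curves hydraulic suitability curves, see [cell_suitabilities()].
#' @param mode HSI combination mode.
#' @return Tibble, one row per date: `date`, `wua_spawn_m2`, `wua_hatch_m2`,
#'   `wua_reduction_pct` (NA when spawning WUA is 0), class-fraction columns
#'   `spawn_<class>` / `hatch_<class>`, and `mode`.
#' @export
habitat_summary <- function(fields, si_l,
                            curves = default_suitability_curves(),
                            mode = c("geometric_mean", "product")) {
  mode <- check_hsi_mode(mode)
  if (!is.data.frame(si_l) || !all(c("date", "si_l") %in% names(si_l))) {
    sh_stop("si_l must have date and si_l columns (see si_l_series())")
  }
  if (nrow(si_l) == 0L) sh_stop("si_l series is empty")
  if (inherits(fields, "hydro_field")) {
    field_for <- function(date) fields
  } else if (is.list(fields) &&
             all(vapply(fields, inherits, logical(1), "hydro_field"))) {
    fdates <- vapply(fields, function(f) as.character(f$date), character(1))
    missing <- setdiff(as.character(si_l$date), fdates)
    if (length(missing)) {
      sh_stop("no hydro_field for date(s): ",
              paste(utils::head(missing, 5L), collapse = ", "))
    }
    field_for <- function(date) fields[[match(as.character(date), fdates)]]
  } else {
    sh_stop("fields must be a hydro_field or a list of hydro_fields")
  }
  rows <- lapply(seq_len(nrow(si_l)), function(i) {
    date <- si_l$date[i]
    suits <- cell_suitabilities(field_for(date), curves = curves,
                                si_l = si_l$si_l[i], mode = mode)
    wua_s <- weighted_usable_area(suits$area_m2, suits$hsi_spawn)
    wua_h <- weighted_usable_area(suits$area_m2, suits$hsi_hatch)
    cat_tab <- class_area_table(suits)
    frac <- c(cat_tab$spawn_fraction, cat_tab$hatch_fraction)
    names(frac) <- c(paste0("spawn_", HSI_CLASSES),
                     paste0("hatch_", HSI_CLASSES))
    c(list(date = date, wua_spawn_m2 = wua_s, wua_hatch_m2 = wua_h,
           wua_reduction_pct =
             if (wua_s > 0) 100 * (wua_s - wua_h) / wua_s else NA_real_),
      as.list(frac))
  })
  out <- do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
  out$mode <- mode
  out
}
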