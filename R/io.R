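#' Read a daily stage series from CSV
#'
#' Expects columns `date` (ISO-8601) and `level_m`. Gaps and duplicate days
#' are rejected with the offending dates named; nothing is silently filled.
#'
#' @param path CSV file path.
#' @return A [stage_series()].
#' @export
read_stage_csv <- function(path) {
  df <- read_checked_csv(path, c("date", "level_m"))
  if (!is.numeric(df$level_m)) sh_stop("level_m must be numeric in ", path)
  stage_series(df$date, df$level_m)
}

#' Write a stage series to CSV
#'
#' @param series a [stage_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_csv <- function(series, path) {
  if (!inherits(series, "stage_series")) {
    sh_stop("series must be a stage_series")
  }
  df <- data.frame(date = format(series$date),
                   level_m = fmt_num(series$level_m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-cell hydraulic field from CSV
#'
#' Expects columns `cell_id`, `area_m2`, `velocity_ms`, `depth_m`, `temp_c`,
#' optionally `date` (one value per file; multi-date long files should be
#' split by the caller). Non-numeric fields, duplicate ids and non-positive
#' areas are rejected with the offending cells named.
#'
#' @param path CSV file path.
#' @param date snapshot date; required when the file has no `date` column.
#' @return A [hydro_field()].
#' @export
read_field_csv <- function(path, date = NULL) {
  need <- c("cell_id", "area_m2", "velocity_ms", "depth_m", "temp_c")
  df <- read_checked_csv(path, need, allow_extra = "date")
  for (col in setdiff(need, "cell_id")) {
    if (!is.numeric(df[[col]])) {
      sh_stop("column ", col, " must be numeric in ", path)
    }
  }
  if (is.null(date)) {
    if (is.null(df$date)) sh_stop("no date column in ", path,
                                  " and no date argument given")
    date <- unique(df$date)
    if (length(date) != 1L) {
      sh_stop(path, " holds multiple dates; read one date per field")
    }
  }
  hydro_field(df[need], date = date)
}

#' Read an egg-deposition depth-frequency table
#'
#' CSV with columns `depth_lo_m`, `depth_hi_m`, `count`, or a JSON file with
#' those arrays (chosen by file extension).
#'
#' @param path CSV or JSON file path.
#' @return A [depth_frequency_table()].
#' @export
read_frequency_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("depth_lo_m", "depth_hi_m", "count")
    if (!all(need %in% names(doc))) {
      sh_stop("frequency-table JSON needs fields: ",
              paste(need, collapse = ", "))
    }
    return(depth_frequency_table(doc$depth_lo_m, doc$depth_hi_m, doc$count))
  }
  df <- read_checked_csv(path, c("depth_lo_m", "depth_hi_m", "count"))
  depth_frequency_table(df$depth_lo_m, df$depth_hi_m, df$count)
}

#' Read and write suitability curves as JSON
#'
#' Curves serialize to a JSON document with `variable`, `units`, `knots`
#' (arrays `x`, `s`), `left_policy`, `right_policy`, written at full
#' precision so write-then-read reproduces the curve exactly.
#'
#' @param curve a `suitability_curve`.
#' @param path JSON file path.
#' @return `read_curve_json()` returns a `suitability_curve`;
#'   `write_curve_json()` returns `path` invisibly.
#' @export
write_curve_json <- function(curve, path) {
  if (!inherits(curve, "suitability_curve")) {
    sh_stop("curve must be a suitability_curve")
  }
  doc <- list(variable = curve$variable, units = curve$units,
              knots = list(x = curve$knots$x, s = curve$knots$s),
              left_policy = curve$left_policy,
              right_policy = curve$right_policy)
  # 17 significant digits: the minimum that round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("variable", "units", "knots", "left_policy", "right_policy")
  if (!all(need %in% names(doc))) {
    sh_stop("curve JSON needs fields: ", paste(need, collapse = ", "))
  }
  new_suitability_curve(doc$variable, doc$units, doc$knots$x, doc$knots$s,
                        doc$left_policy, doc$right_policy)
}

#' Write a habitat summary table to CSV
#'
#' Fixed column order and 6-significant-digit float formatting so identical
#' inputs give byte-identical files.
#'
#' @param summary a [habitat_summary()] tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  if (!is.data.frame(summary) || is.null(summary$date)) {
    sh_stop("summary must be a habitat_summary() table")
  }
  df <- as.data.frame(summary)
  df$date <- format(df$date)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: deterministic 6-significant-digit formatting
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "fg", flag = "#",
                                 digits = 6, width = 1))
}

# internal: CSV reader that rejects missing columns instead of coercing
read_checked_csv <- function(path, need, allow_extra = character()) {
  if (!file.exists(path)) sh_stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) sh_stop("could not parse ", path, ": ",
                                conditionMessage(e))
  )
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    sh_stop(path, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}
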