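#' Egg-deposition depth-frequency table
#'
#' Container for binned counts of egg-deposition depths, the empirical basis
#' of the water-level-fluctuation suitability curve. Bins must be contiguous,
#' non-overlapping and strictly ascending; counts are non-negative with a
#' positive total, so the cumulative fraction reaches exactly 1 at the last
#' upper edge.
#'
#' @param lower,upper numeric vectors of bin edges in metres (`lower < upper`,
#'   bins contiguous: each `lower[i + 1] == upper[i]`).
#' @param counts non-negative integer counts per bin; total must be positive.
#' @return A `depth_frequency_table` object.
#' @seealso [make_drawdown_curve()], [egg_depth_reference()]
#' @export
#' @examples
#' depth_frequency_table(c(0, 0.2, 0.3), c(0.2, 0.3, 0.4), c(1, 7, 27))
depth_frequency_table <- function(lower, upper, counts) {
  assert_finite(lower, "bin lower edges")
  assert_finite(upper, "bin upper edges")
  assert_finite(counts, "counts")
  n <- length(counts)
  if (length(lower) != n || length(upper) != n || n == 0L) {
    sh_stop("lower, upper and counts must be equal-length, non-empty vectors")
  }
  if (any(lower >= upper)) sh_stop("every bin needs lower < upper")
  if (n > 1L && any(abs(lower[-1L] - upper[-n]) > 1e-9)) {
    sh_stop("bins must be contiguous and strictly ascending")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    sh_stop("counts must be non-negative integers")
  }
  if (sum(counts) <= 0) sh_stop("total count must be positive")
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         counts = as.integer(counts), total = as.integer(sum(counts))),
    class = "depth_frequency_table"
  )
}

#' @export
print.depth_frequency_table <- function(x, ...) {
  cat("<depth_frequency_table> ", length(x$counts), " bins, ",
      x$total, " observations, depths ", x$lower[1L], "-",
      x$upper[length(x$upper)], " m\n", sep = "")
  invisible(x)
}

#' Per-bin and cumulative egg-depth proportions
#'
#' @param table a [depth_frequency_table()].
#' @return A tibble with `depth_lo_m`, `depth_hi_m`, `count`, `proportion`
#'   (count / total) and `cum_proportion` (cumulative fraction at the bin's
#'   upper edge). Proportions are exact fractions of the raw counts, not
#'   re-rounded percentages.
#' @export
bin_proportions <- function(table) {
  if (!inherits(table, "depth_frequency_table")) {
    sh_stop("table must be a depth_frequency_table")
  }
  tibble::tibble(
    depth_lo_m = table$lower,
    depth_hi_m = table$upper,
    count = table$counts,
    proportion = table$counts / table$total,
    cum_proportion = cumsum(table$counts) / table$total
  )
}

#' Reference egg-deposition depth distribution
#'
#' The packaged depth-frequency table of adhesive egg deposition for carp
#' (*Cyprinus carpio*) and crucian carp (*Carassius auratus*): 163 field
#' observations in seven bins between 0 and 0.8 m, with the mode at
#' 0.4--0.5 m. No attachment occurs beyond 0.8 m depth.
#'
#' @return A [depth_frequency_table()].
#' @export
#' @examples
#' tab <- egg_depth_reference()
#' bin_proportions(tab)
egg_depth_reference <- function() {
  path <- system.file("extdata", "egg_depth_frequency.csv",
                      package = "stickyhab", mustWork = TRUE)
  read_frequency_table(path)
}

new_suitability_curve <- function(variable, units, x, s,
                                  left_policy, right_policy) {
  assert_finite(x, "knot x values")
  assert_unit_interval(s, "knot suitability values")
  if (length(x) != length(s) || length(x) < 2L) {
    sh_stop("a curve needs at least two (x, s) knots of equal length")
  }
  if (any(diff(x) <= 0)) sh_stop("knot x values must be strictly increasing")
  assert_unit_interval(left_policy, "left_policy")
  assert_unit_interval(right_policy, "right_policy")
  structure(
    list(variable = variable, units = units,
         knots = tibble::tibble(x = as.numeric(x), s = as.numeric(s)),
         left_policy = as.numeric(left_policy),
         right_policy = as.numeric(right_policy)),
    class = "suitability_curve"
  )
}

#' @export
print.suitability_curve <- function(x, ...) {
  cat("<suitability_curve> ", x$variable, " [", x$units, "], ",
      nrow(x$knots), " knots on [", x$knots$x[1L], ", ",
      x$knots$x[nrow(x$knots)], "], policies (",
      x$left_policy, ", ", x$right_policy, ")\n", sep = "")
  invisible(x)
}

#' Trapezoidal habitat suitability curve
#'
#' Builds the standard trapezoidal preference curve used for flow velocity,
#' water depth and water temperature: suitability 1 over the optimal range,
#' falling linearly to 0 at the support limits, and 0 beyond them. When an
#' optimal edge coincides with a support edge the limb on that side is
#' degenerate and the shared edge keeps suitability 1 (e.g. a species fully
#' suited to still water has s(0) = 1 for velocity); evaluation beyond that
#' edge clamps to the edge value.
#'
#' @param variable name of the environmental variable (e.g. `"velocity"`).
#' @param support length-2 numeric, the observed range outside which
#'   suitability is 0.
#' @param optimal length-2 numeric, the range assigned suitability 1; must lie
#'   within `support`.
#' @param units unit string, for labelling and serialized curves.
#' @return A `suitability_curve`.
#' @export
#' @examples
#' depth_curve <- make_trapezoid_curve("depth", c(0.2, 0.8), c(0.4, 0.6), "m")
#' evaluate_curve(depth_curve, c(0.3, 0.5, 0.9))
make_trapezoid_curve <- function(variable, support, optimal, units = "") {
  assert_finite(support, "support")
  assert_finite(optimal, "optimal")
  if (length(support) != 2L || length(optimal) != 2L) {
    sh_stop("support and optimal must each be length-2 (lo, hi)")
  }
  if (support[1L] >= support[2L] || optimal[1L] > optimal[2L]) {
    sh_stop("inverted range: need support lo < hi and optimal lo <= hi")
  }
  if (optimal[1L] < support[1L] || optimal[2L] > support[2L]) {
    sh_stop("optimal range must lie within the support range")
  }
  x <- c(support[1L], optimal[1L], optimal[2L], support[2L])
  s <- c(0, 1, 1, 0)
  # degenerate limb: optimal edge on the support edge keeps suitability 1
  keep <- !duplicated(x)
  s <- ifelse(x %in% optimal, 1, s)[keep]
  x <- x[keep]
  if (length(x) < 2L) sh_stop("support collapses to a point")
  new_suitability_curve(variable, units, x, s,
                        left_policy = s[1L],
                        right_policy = s[length(s)])
}

#' Drawdown (water-level-fluctuation) suitability curve
#'
#' Converts an egg-deposition depth-frequency table into the suitability
#' curve for the cumulative water-level drop over the incubation window. An
#' egg deposited at depth z survives a drop d iff z > d, so the suitability
#' at drop d is the surviving egg fraction 1 - F(d), with F the cumulative
#' deposition-depth distribution computed from the raw counts (uniform within
#' bins, hence piecewise linear between bin edges). s(0) = 1, s reaches 0 at
#' the deepest deposition depth, rising water (negative drop) keeps s = 1.
#'
#' @param table a [depth_frequency_table()].
#' @return A `suitability_curve` for variable `"five_day_drop"`, knots at
#'   drop 0 and every bin upper edge, monotonically non-increasing.
#' @export
#' @examples
#' curve <- make_drawdown_curve(egg_depth_reference())
#' evaluate_curve(curve, c(0, 0.2, 0.5, 1.0))
make_drawdown_curve <- function(table) {
  if (!inherits(table, "depth_frequency_table")) {
    sh_stop("table must be a depth_frequency_table")
  }
  cum <- cumsum(table$counts) / table$total
  x <- c(min(table$lower[1L], 0), table$upper)
  s <- c(1, 1 - cum)
  # a first bin not starting at 0 would leave drops below it at s = 1
  if (table$lower[1L] > 0) {
    x <- c(0, table$lower[1L], table$upper)
    s <- c(1, 1, 1 - cum)
  }
  s[length(s)] <- 0  # exact, cum fraction is 1 by construction
  new_suitability_curve("five_day_drop", "m", x, s,
                        left_policy = 1, right_policy = 0)
}

#' Evaluate a suitability curve
#'
#' Exact linear interpolation between knots; outside the knot span the
#' curve's constant left/right policy applies. Non-finite inputs are an
#' error, never silently mapped to 0.
#'
#' @param curve a `suitability_curve`.
#' @param x numeric scalar or vector of environmental values.
#' @return Numeric vector of suitabilities in `[0, 1]`, same length as `x`.
#' @export
evaluate_curve <- function(curve, x) {
  if (!inherits(curve, "suitability_curve")) {
    sh_stop("curve must be a suitability_curve")
  }
  assert_finite(x, "evaluation points")
  kx <- curve$knots$x
  ks <- curve$knots$s
  out <- stats::approx(kx, ks, xout = x, method = "linear",
                       yleft = curve$left_policy,
                       yright = curve$right_policy, ties = "ordered")$y
  pmin(1, pmax(0, out))
}

#' @export
#' @rdname evaluate_curve
#' @param object a `suitability_curve` (predict-method alias).
#' @param ... unused.
predict.suitability_curve <- function(object, x, ...) {
  evaluate_curve(object, x)
}

#' Default hydraulic suitability curves
#'
#' The trapezoidal curves for the three spawning-phase factors, with the
#' field-derived ranges for carp and crucian carp: velocity support
#' 0--0.5 m/s with optimum 0--0.2 m/s (still-water preference; degenerate
#' left limb), depth support 0.2--0.8 m with optimum 0.4--0.6 m, temperature
#' support 15--30 \eqn{^\circ}C with optimum 20--23 \eqn{^\circ}C.
#'
#' @return Named list with elements `velocity`, `depth`, `temperature`.
#' @export
default_suitability_curves <- function() {
  list(
    velocity = make_trapezoid_curve("velocity", c(0, 0.5), c(0, 0.2), "m/s"),
    depth = make_trapezoid_curve("depth", c(0.2, 0.8), c(0.4, 0.6), "m"),
    temperature = make_trapezoid_curve("temperature", c(15, 30), c(20, 23),
                                       "degC")
  )
}
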