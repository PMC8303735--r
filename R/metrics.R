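#' Normalized dynamic ratio of a time series
#'
#' Divides a series elementwise by its first value, the convention used to
#' compare dry-mass and size responses to an osmotic challenge.
#'
#' @param series Numeric vector; the first element must be positive.
#' @return Series of ratios, first element 1.
#' @export
normalized_ratio <- function(series) {
  if (length(series) < 1L) stop("empty series")
  if (!is.finite(series[1L]) || series[1L] <= 0)
    stop("baseline (first element) must be positive")
  series / series[1L]
}

#' Maximum relative change of a series
#'
#' `(max - min) / mean`, the repeatability statistic used for wafer,
#' fixed-cell and osmotic measurements. Permutation-invariant; zero for a
#' constant series.
#'
#' @param series Numeric vector with positive mean.
#' @return Fraction (not percent).
#' @export
max_relative_change <- function(series) {
  if (length(series) < 1L) stop("empty series")
  mu <- mean(series)
  if (!is.finite(mu) || mu <= 0) stop("series mean must be positive")
  (max(series) - min(series)) / mu
}

#' Two-phase growth rates of a mass curve
#'
#' Splits the curve at the breakpoint giving the best two-segment
#' piecewise-linear least-squares fit (each segment an ordinary
#' regression on its own points, candidate breakpoints scanned
#' exhaustively), then reports each phase's fractional growth
#' `(mass_end - mass_start) / mass_start`.
#'
#' @param mass Numeric vector of masses (pg), length at least 3.
#' @param timepoints Optional numeric vector of times; default equally
#'   spaced.
#' @return A list with `phase1`, `phase2` (fractions), `boundary_index`,
#'   and `sse` of the winning fit.
#' @export
growth_rates <- function(mass, timepoints = seq_along(mass)) {
  n <- length(mass)
  if (n < 3L) stop("need at least 3 timepoints")
  if (length(timepoints) != n || any(diff(timepoints) <= 0))
    stop("'timepoints' must be increasing and match 'mass'")
  seg_sse <- function(idx) {
    if (length(idx) < 2L) return(0)
    f <- stats::lm.fit(cbind(1, timepoints[idx]), mass[idx])
    sum(f$residuals^2)
  }
  cands <- 2:(n - 1L)
  sse <- vapply(cands, function(k)
    seg_sse(1:k) + seg_sse(k:n), numeric(1))
  k <- cands[which.min(sse)]
  if (mass[1L] <= 0 || mass[k] <= 0) stop("phase start mass must be positive")
  list(phase1 = (mass[k] - mass[1L]) / mass[1L],
       phase2 = (mass[n] - mass[k]) / mass[k],
       boundary_index = k, sse = min(sse))
}

#' Nuclear-to-cytoplasmic dry-mass ratio
#'
#' The printed group means of the source instrument's heterogeneity study
#' do not pin down the convention, so both are available:
#' `"cytoplasmic"` (default) divides nuclear by cytoplasmic mass,
#' `"total"` divides nuclear by total mass.
#'
#' @param nuclear,cytoplasmic Masses (pg).
#' @param convention `"cytoplasmic"` or `"total"`.
#' @return Dimensionless ratio.
#' @export
nc_ratio <- function(nuclear, cytoplasmic,
                     convention = c("cytoplasmic", "total")) {
  convention <- match.arg(convention)
  denom <- switch(convention, cytoplasmic = cytoplasmic,
                  total = nuclear + cytoplasmic)
  if (any(denom <= 0)) stop("denominator mass must be positive")
  nuclear / denom
}

#' Population standard deviation of nuclear density
#'
#' Standard deviation (population convention, divisor `n`) of the
#' dry-mass density over the nucleus voxels of the in-focus slice; the
#' heterogeneity statistic that discriminated chemotherapy-surviving
#' cells.
#'
#' @param density_map Density matrix (g/mL).
#' @param nucleus_mask Boolean matrix; must select at least one voxel.
#' @return Standard deviation in g/mL.
#' @export
nuclear_density_sd <- function(density_map, nucleus_mask) {
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  x <- density_map[nucleus_mask]
  sqrt(mean((x - mean(x))^2))
}

#' Two-group comparison of a single-cell metric
#'
#' Welch's two-sided t-test by default (Mann-Whitney available), with an
#' exact-equality shortcut for the degenerate zero-variance case.
#'
#' @param x,y Numeric vectors (e.g. live and dead groups), length >= 2
#'   each.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return A list with `mean_x`, `mean_y`, `difference` (`mean_x -
#'   mean_y`) and `p_value`.
#' @export
compare_groups <- function(x, y, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per group")
  out <- list(mean_x = mean(x), mean_y = mean(y),
              difference = mean(x) - mean(y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    out$p_value <- if (mean(x) == mean(y)) 1 else 0
    return(out)
  }
  out$p_value <- switch(method,
    welch = stats::t.test(x, y, var.equal = FALSE)$p.value,
    wilcoxon = stats::wilcox.test(x, y, exact = FALSE)$p.value)
  out
}

#' Reference thickness measurements of the calibration layers
#'
#' Published validation table for six silica calibration layers: nominal
#' (theoretical) thickness, repeated-measurement mean and standard
#' deviation, all in nm. Used to recompute the instrument's sensitivity
#' arithmetic.
#'
#' @return A data.frame with columns `nominal`, `measured`, `sd`.
#' @export
wafer_reference_measurements <- function() {
  data.frame(
    nominal  = c(285, 300, 500, 800, 1000, 2000),
    measured = c(285.00, 300.49, 500.00, 799.99, 999.01, 1999.00),
    sd       = c(0.81, 0.78, 0.81, 0.79, 0.81, 0.80))
}

#' Sensitivity arithmetic from a wafer validation table
#'
#' From repeated thickness measurements of calibration layers:
#' the maximal absolute measured-vs-nominal error, the coefficient of
#' determination (squared Pearson correlation), the thickness sensitivity
#' (three times the maximal standard deviation), and the optical path
#' difference sensitivity (thickness sensitivity times the layer RI).
#'
#' @param table A data.frame as returned by
#'   [wafer_reference_measurements()].
#' @param layer_ri Mean refractive index of the layer material (silica,
#'   1.45).
#' @param max_sd Maximal repeated-measurement standard deviation (nm);
#'   default the largest value in `table`. The published summary of the
#'   reference measurements quotes 0.80 nm, one rounding step below the
#'   largest per-layer value in the same source (0.81 nm); pass
#'   `max_sd = 0.80` to reproduce the published sensitivity arithmetic.
#' @return A list with `max_abs_error`, `r_squared`,
#'   `thickness_sensitivity`, `opd_sensitivity` (all nm except
#'   `r_squared`).
#' @export
wafer_sensitivity <- function(table = wafer_reference_measurements(),
                              layer_ri = 1.45, max_sd = max(table$sd)) {
  ts <- 3 * max_sd
  list(max_abs_error = max(abs(table$measured - table$nominal)),
       r_squared = stats::cor(table$measured, table$nominal)^2,
       thickness_sensitivity = ts,
       opd_sensitivity = ts * layer_ri)
}
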