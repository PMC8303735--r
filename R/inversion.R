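#' Search grid specification for the ergodic inversion
#'
#' Defines the exhaustive-search grids. Defaults follow the instrument
#' protocol: contrast dn from -0.3 to 0.3 in steps of 1e-4, axial offset
#' dz from -300 nm to 300 nm in steps of 0.1 nm, and (for wafer mode) a
#' thickness axis 0 to 2500 nm in steps of 0.1 nm.
#'
#' @param dn_min,dn_max,dn_step Contrast grid (dimensionless).
#' @param dz_min,dz_max,dz_step Axial-offset grid (nm).
#' @param t_min,t_max,t_step Thickness grid (nm), wafer mode only.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(dn_min = -0.3, dn_max = 0.3, dn_step = 1e-4,
                      dz_min = -300, dz_max = 300, dz_step = 0.1,
                      t_min = 0, t_max = 2500, t_step = 0.1) {
  chk <- function(lo, hi, st, what) {
    if (!(lo < hi) || st <= 0)
      stop(sprintf("invalid %s grid: need min < max and step > 0", what))
  }
  chk(dn_min, dn_max, dn_step, "dn")
  chk(dz_min, dz_max, dz_step, "dz")
  chk(t_min, t_max, t_step, "thickness")
  structure(list(dn_min = dn_min, dn_max = dn_max, dn_step = dn_step,
                 dz_min = dz_min, dz_max = dz_max, dz_step = dz_step,
                 t_min = t_min, t_max = t_max, t_step = t_step),
            class = "grid_spec")
}

# number of grid points along one axis (min + i*step, i = 0..n-1)
grid_n <- function(lo, hi, st) as.integer(floor((hi - lo) / st + 1e-9)) + 1L

#' Fit error between measured and modeled normalized intensities
#'
#' Sum of squared differences across wavelengths,
#' `sum((Ihat_meas - Ihat_model)^2)`. Zero iff the vectors are equal;
#' symmetric in its arguments.
#'
#' @param measured,modeled Equal-length numeric vectors over the same
#'   wavelength set.
#' @return Non-negative scalar.
#' @export
fit_error <- function(measured, modeled) {
  if (length(measured) != length(modeled))
    stop("'measured' and 'modeled' must have the same length")
  sum((measured - modeled)^2)
}

#' Exhaustive ("ergodic") search for contrast and axial offset
#'
#' Recovers the pair (dn, dz) minimising [fit_error()] between a measured
#' four-wavelength normalized-intensity vector and the uniform-slab forward
#' model, over the full Cartesian grid of `grid`. Ties are broken
#' deterministically: smallest `|dz|`, then smallest `|dn|`, then
#' lexicographic order. The default path is an exact algebraic reduction
#' (for fixed dz the error is quadratic in dn, so only the grid neighbours
#' of the per-dz optimum need evaluation) whose result is identical to a
#' literal scan of every grid point.
#'
#' @param measured Normalized intensities, one per wavelength.
#' @param optics An [optical_stack()].
#' @param grid A [grid_spec()].
#' @param slab Slab extent `c(a, b)` of the pixel column (nm), the nominal
#'   geometry the per-pixel model assumes.
#' @param wl A [wavelength_set()] matching `measured`.
#' @return A list with `delta_n`, `delta_z` (nm), `residual`, and
#'   `degenerate` (`TRUE` when the measurement is consistent with dn = 0,
#'   in which case dz is unidentifiable and reported as 0).
#' @examples
#' opt <- optical_stack()
#' m <- slab_normalized_intensity(0, 500, 0.05, 50, opt$n1, wavelength_set())
#' ergodic_search(m, opt, grid_spec(), slab = c(0, 500))
#' @export
ergodic_search <- function(measured, optics, grid, slab,
                           wl = wavelength_set()) {
  stopifnot(inherits(optics, "optical_stack"), inherits(grid, "grid_spec"))
  if (length(measured) != length(wl))
    stop("'measured' must have one value per wavelength")
  if (length(slab) != 2L || !(slab[1] < slab[2]))
    stop("'slab' must be c(a, b) with a < b (nm)")
  res <- cpp_search_dn_dz(as.numeric(measured) - 1, as.numeric(unclass(wl)),
                          optics$n1, slab[1], slab[2],
                          grid$dn_min, grid$dn_step,
                          grid_n(grid$dn_min, grid$dn_max, grid$dn_step),
                          grid$dz_min, grid$dz_step,
                          grid_n(grid$dz_min, grid$dz_max, grid$dz_step))
  degen <- res[["delta_n"]] == 0
  list(delta_n = res[["delta_n"]],
       delta_z = if (degen) 0 else res[["delta_z"]],
       residual = res[["residual"]],
       degenerate = degen)
}

#' Per-pixel inversion of an interferogram stack
#'
#' Applies [ergodic_search()] to every pixel of each requested z-slice and
#' assembles contrast, axial-offset, residual and refractive-index maps.
#' For multi-slice stacks the in-focus slice is chosen with
#' [select_focus()].
#'
#' @param stack An [interferogram_stack()].
#' @param optics An [optical_stack()].
#' @param grid A [grid_spec()].
#' @param slab Nominal slab extent `c(a, b)` (nm) assumed for every pixel
#'   column.
#' @param slices Which z-slices to invert (default all).
#' @param residual_threshold Pixels with residual above this value are
#'   flagged in `flagged_map`.
#' @param noise_floor Contrast magnitude below which a pixel is treated as
#'   background when building the focus-selection mask; default three dn
#'   grid steps.
#' @return For a single slice, an object of class `recovered_field` with
#'   per-pixel maps `delta_n_map`, `delta_z_map`, `residual_map`, `ri_map`
#'   (`n = n1 (1 + dn)`), `degenerate_map` and `flagged_map`. For several
#'   slices, a `recovered_stack`: a list of `recovered_field`s plus the
#'   chosen `focus_index`.
#' @export
invert_image <- function(stack, optics, grid, slab,
                         slices = NULL, residual_threshold = Inf,
                         noise_floor = 3 * grid$dn_step) {
  stopifnot(inherits(stack, "interferogram_stack"))
  if (length(stack$wl) < 2L)
    stop("inversion requires at least two wavelengths")
  if (all(stack$images == 0)) stop("all-zero image: nothing to invert")
  if (is.null(slices)) slices <- seq_along(stack$z_positions)
  fields <- lapply(slices, function(zi) {
    ihat <- normalized_slice(stack, zi)
    d <- dim(ihat)
    M <- matrix(ihat, nrow = d[1] * d[2], ncol = d[3])
    res <- cpp_invert_slab_image(M, as.numeric(unclass(stack$wl)),
                                 optics$n1, slab[1], slab[2],
                                 grid$dn_min, grid$dn_step,
                                 grid_n(grid$dn_min, grid$dn_max, grid$dn_step),
                                 grid$dz_min, grid$dz_step,
                                 grid_n(grid$dz_min, grid$dz_max, grid$dz_step))
    dn <- matrix(res[, 1], d[1], d[2])
    degen <- dn == 0
    dz <- matrix(res[, 2], d[1], d[2])
    dz[degen] <- 0
    rs <- matrix(res[, 3], d[1], d[2])
    structure(list(delta_n_map = dn, delta_z_map = dz, residual_map = rs,
                   ri_map = optics$n1 * (1 + dn), degenerate_map = degen,
                   flagged_map = rs > residual_threshold,
                   z_position = stack$z_positions[zi], slab = slab,
                   pixel_pitch = stack$pixel_pitch, optics = optics,
                   grid = grid, noise_floor = noise_floor),
              class = "recovered_field")
  })
  if (length(fields) == 1L) return(fields[[1L]])
  structure(list(slices = fields,
                 focus_index = select_focus(fields, noise_floor = noise_floor),
                 z_positions = stack$z_positions[slices]),
            class = "recovered_stack")
}

#' @export
print.recovered_field <- function(x, ...) {
  cat(sprintf("<recovered_field> %d x %d px at z = %g nm; dn in [%g, %g]\n",
              nrow(x$delta_n_map), ncol(x$delta_n_map), x$z_position,
              min(x$delta_n_map), max(x$delta_n_map)))
  invisible(x)
}

#' @export
print.recovered_stack <- function(x, ...) {
  cat(sprintf("<recovered_stack> %d slices, in-focus index %d\n",
              length(x$slices), x$focus_index))
  invisible(x)
}

#' In-focus slice of a recovered field
#'
#' Returns the `recovered_field` of the in-focus slice (the object itself
#' when it is single-slice).
#'
#' @param x A `recovered_field` or `recovered_stack`.
#' @return A `recovered_field`.
#' @export
focus_field <- function(x) {
  if (inherits(x, "recovered_field")) return(x)
  if (inherits(x, "recovered_stack")) return(x$slices[[x$focus_index]])
  stop("not a recovered field or stack")
}

#' Select the in-focus slice of a recovered z-stack
#'
#' Picks the slice with the smallest median fit residual over the sample
#' mask (pixels whose recovered contrast magnitude exceeds the noise
#' floor, pooled across slices; all pixels when that mask is empty). Ties
#' go to the lower slice index.
#'
#' @param fields List of `recovered_field` objects (one per slice).
#' @param mask Optional boolean matrix restricting the residual statistic.
#' @param noise_floor Contrast magnitude defining sample pixels when
#'   `mask` is not given.
#' @return Integer slice index.
#' @export
select_focus <- function(fields, mask = NULL, noise_floor = NULL) {
  if (length(fields) == 0L) stop("empty slice list")
  if (is.null(mask)) {
    if (is.null(noise_floor)) noise_floor <- fields[[1L]]$noise_floor
    mask <- Reduce(`|`, lapply(fields, function(f)
      abs(f$delta_n_map) > noise_floor))
    if (!any(mask)) mask <- !mask
  }
  med <- vapply(fields, function(f)
    stats::median(f$residual_map[mask]), numeric(1))
  which.min(med)  # which.min returns the first (lowest-index) minimum
}

#' Thickness inversion for a uniform layer of known contrast
#'
#' Wafer-mode search: the layer contrast is known (silica against the
#' ambient medium, scaled by the carrier index) and the exhaustive search
#' runs over (thickness, dz) instead of (dn, dz), using the closed-form
#' slab model `[0, t]`. Ties are broken towards smaller `|dz|`, then
#' smaller thickness.
#'
#' @param measured Normalized intensities, one per wavelength.
#' @param optics An [optical_stack()]; `n1` is the layer's carrier index.
#' @param grid A [grid_spec()] supplying the thickness and dz axes.
#' @param dn_layer Known layer contrast; defaults to
#'   `(n1 - n0) / n1`, the layer-vs-ambient contrast expressed in the
#'   model's fractional convention.
#' @param wl A [wavelength_set()].
#' @return A list with `thickness` (nm), `delta_z` (nm), `residual`, and
#'   `degenerate` (`TRUE` for a zero-thickness fit, where dz is
#'   unidentifiable and reported as 0).
#' @export
invert_wafer <- function(measured, optics, grid,
                         dn_layer = (optics$n1 - optics$n0) / optics$n1,
                         wl = wavelength_set()) {
  stopifnot(inherits(optics, "optical_stack"), inherits(grid, "grid_spec"))
  if (length(measured) != length(wl))
    stop("'measured' must have one value per wavelength")
  res <- cpp_search_wafer(as.numeric(measured) - 1,
                          as.numeric(unclass(wl)), optics$n1, dn_layer,
                          grid$t_min, grid$t_step,
                          grid_n(grid$t_min, grid$t_max, grid$t_step),
                          grid$dz_min, grid$dz_step,
                          grid_n(grid$dz_min, grid$dz_max, grid$dz_step))
  degen <- res[["thickness"]] == 0
  list(thickness = res[["thickness"]],
       delta_z = if (degen) 0 else res[["delta_z"]],
       residual = res[["residual"]],
       degenerate = degen)
}

#' Sample-support mask of a recovered field
#'
#' Pixels whose recovered contrast magnitude exceeds the noise floor
#' (default three dn grid steps). This is the gating that keeps empty
#' medium out of dry-mass integrals: a background pixel recovers dn = 0,
#' i.e. RI = n1, whose Gladstone-Dale density is far from zero.
#'
#' @param field A `recovered_field`.
#' @param noise_floor Contrast magnitude threshold.
#' @return Boolean matrix.
#' @export
sample_mask <- function(field, noise_floor = field$noise_floor) {
  abs(field$delta_n_map) > noise_floor
}
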