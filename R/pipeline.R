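#' Measure single cells in an interferogram stack
#'
#' End-to-end pipeline: per-pixel ergodic inversion of each z-slice,
#' in-focus slice selection, cell labelling, nucleus segmentation, and the
#' per-cell metric table (total / nuclear / cytoplasmic dry mass, N/C
#' ratio, footprint size, nuclear density SD). Cells are labelled by
#' 8-connected components of the cell support in raster order, so labels
#' are stable across reruns.
#'
#' @param stack An [interferogram_stack()].
#' @param optics An [optical_stack()].
#' @param grid A [grid_spec()].
#' @param slab Nominal column slab extent `c(a, b)` (nm).
#' @param threshold Nucleus RI threshold.
#' @param erosion_radius,min_size,dilation_radius Segmentation parameters,
#'   see [segment_nucleus()].
#' @param nc_convention N/C ratio convention, see [nc_ratio()].
#' @return A data.frame with one row per detected cell: `cell_id`,
#'   `size_px`, `total_mass_pg`, `nuclear_mass_pg`, `cytoplasmic_mass_pg`,
#'   `nc_ratio`, `nuclear_density_sd`, `focus_index`. No cells found
#'   yields an empty table with a warning. The field and masks are
#'   attached as attributes `field` and `masks`.
#' @export
measure_cells <- function(stack, optics, grid = grid_spec(), slab,
                          threshold = 1.42, erosion_radius = 2,
                          min_size = 20, dilation_radius = 3,
                          nc_convention = "cytoplasmic") {
  rec <- invert_image(stack, optics, grid, slab)
  field <- focus_field(rec)
  focus_index <- if (inherits(rec, "recovered_stack")) rec$focus_index else 1L
  cell_mask <- cell_support(field, min_size = min_size)
  empty <- data.frame(cell_id = integer(), size_px = integer(),
                      total_mass_pg = numeric(), nuclear_mass_pg = numeric(),
                      cytoplasmic_mass_pg = numeric(), nc_ratio = numeric(),
                      nuclear_density_sd = numeric(), focus_index = integer())
  if (!any(cell_mask)) {
    warning("no cells found")
    return(empty)
  }
  labels <- EBImage::bwlabel(cell_mask * 1)
  seg <- segment_nucleus(field, threshold = threshold,
                         erosion_radius = erosion_radius,
                         min_size = min_size,
                         dilation_radius = dilation_radius,
                         cell_mask = cell_mask)
  dmap <- field_density(field, cell_mask = cell_mask)
  rows <- lapply(seq_len(max(labels)), function(id) {
    cm <- labels == id
    nm <- seg$nucleus_mask & cm
    tot <- integrate_mass(dmap, roi = cm)$total_mass
    nuc <- if (any(nm)) integrate_mass(dmap, roi = nm)$total_mass else 0
    cyt <- tot - nuc
    data.frame(
      cell_id = id, size_px = sum(cm), total_mass_pg = tot,
      nuclear_mass_pg = nuc, cytoplasmic_mass_pg = cyt,
      nc_ratio = if (cyt > 0) nc_ratio(nuc, cyt, nc_convention) else NA_real_,
      nuclear_density_sd = if (any(nm))
        nuclear_density_sd(dmap$density_map, nm) else NA_real_,
      focus_index = focus_index)
  })
  out <- do.call(rbind, rows)
  attr(out, "field") <- field
  attr(out, "masks") <- seg
  out
}

#' Recover per-sphere refractive indices from a microsphere phantom
#'
#' Inverts the phantom image over the slab `[0, diameter]` (the central
#' chord of each sphere) and reads the recovered refractive index at the
#' known sphere centres, the standard calibration protocol for accuracy
#' studies.
#'
#' @param phantom Output of [make_microsphere_field()].
#' @param grid A [grid_spec()].
#' @return A data.frame with one row per sphere: `sphere`, `ri_recovered`,
#'   `ri_true`.
#' @export
measure_spheres <- function(phantom, grid = grid_spec()) {
  stopifnot(is.list(phantom), phantom$truth$kind == "microsphere")
  field <- invert_image(phantom$stack, phantom$optics, grid,
                        slab = c(0, phantom$truth$diameter))
  data.frame(sphere = seq_len(nrow(phantom$truth$centres)),
             ri_recovered = field$ri_map[phantom$truth$centres],
             ri_true = phantom$truth$ri_true)
}

#' Run the measurement pipeline over a phantom time series
#'
#' Applies [measure_cells()] to each timepoint of an osmotic or growth
#' series and collects the whole-image totals (series phantoms hold a
#' single cell).
#'
#' @param series Output of [make_osmotic_series()] or
#'   [make_growth_series()].
#' @param grid A [grid_spec()].
#' @param ... Passed on to [measure_cells()].
#' @return A data.frame with one row per timepoint: `t`, `total_mass_pg`,
#'   `nuclear_mass_pg`, `size_px`.
#' @export
measure_series <- function(series, grid = grid_spec(), ...) {
  rows <- lapply(seq_along(series$phantoms), function(t) {
    ph <- series$phantoms[[t]]
    tab <- measure_cells(ph$stack, ph$optics, grid,
                         slab = c(0, ph$truth$height * 1000), ...)
    data.frame(t = t,
               total_mass_pg = sum(tab$total_mass_pg),
               nuclear_mass_pg = sum(tab$nuclear_mass_pg),
               size_px = sum(tab$size_px))
  })
  do.call(rbind, rows)
}
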