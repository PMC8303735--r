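#' Gladstone-Dale conversion of refractive index to dry-mass density
#'
#' `rho = (n - nw) / alpha`, elementwise. With `nw = 1.333` and
#' `alpha = 0.18 mL/g` a cytoplasmic RI of 1.36 maps to 0.15 g/mL.
#'
#' @param ri_map Numeric vector/matrix/array of refractive indices.
#' @param optics An [optical_stack()] supplying `nw` and `alpha`.
#' @return Density in g/mL, same shape as `ri_map`.
#' @export
gladstone_dale <- function(ri_map, optics) {
  stopifnot(inherits(optics, "optical_stack"))
  (ri_map - optics$nw) / optics$alpha
}

#' Dry-mass density map with voxel geometry
#'
#' Couples a per-pixel density map (g/mL) with the voxel geometry needed
#' to integrate mass: lateral pixel area (um^2) and axial voxel extent
#' (um). One voxel of 1 um^3 at 1 g/mL holds exactly 1 pg of dry mass.
#'
#' @param density_map Numeric matrix, g/mL; must be finite.
#' @param voxel_area Pixel area at the sample plane (um^2).
#' @param slice_thickness Axial voxel extent (um).
#' @param cell_mask Optional boolean support of the cell.
#' @return An object of class `drymass_map`.
#' @export
drymass_map <- function(density_map, voxel_area, slice_thickness,
                        cell_mask = NULL) {
  if (any(!is.finite(density_map))) stop("density must be finite")
  if (voxel_area <= 0 || slice_thickness <= 0)
    stop("voxel geometry must be positive")
  if (!is.null(cell_mask) && !identical(dim(cell_mask), dim(density_map)))
    stop("'cell_mask' must match the density map dimensions")
  structure(list(density_map = density_map, voxel_area = voxel_area,
                 slice_thickness = slice_thickness, cell_mask = cell_mask),
            class = "drymass_map")
}

#' Density map of a recovered field
#'
#' Convenience wrapper: applies [gladstone_dale()] to the RI map of a
#' `recovered_field` and attaches the voxel geometry. The axial extent
#' defaults to the nominal slab height the inversion assumed, so that
#' integrating the in-focus map yields column mass directly.
#'
#' @param field A `recovered_field`.
#' @param slice_thickness Axial voxel extent (um); default the slab height.
#' @param cell_mask Optional boolean cell support.
#' @return A [drymass_map()].
#' @export
field_density <- function(field, slice_thickness = NULL, cell_mask = NULL) {
  stopifnot(inherits(field, "recovered_field"))
  if (is.null(slice_thickness))
    slice_thickness <- diff(field$slab) / 1000  # nm -> um
  drymass_map(gladstone_dale(field$ri_map, field$optics),
              voxel_area = field$pixel_pitch^2,
              slice_thickness = slice_thickness, cell_mask = cell_mask)
}

#' Integrate dry mass over a region of interest
#'
#' `mass = sum_{voxels in roi} rho * voxel_area * slice_thickness`, with
#' g/mL x um^3 = pg. When `regions` (an integer label matrix) is given,
#' per-region masses are returned as well; labels partitioning the ROI sum
#' exactly to the total.
#'
#' @param map A [drymass_map()].
#' @param roi Boolean matrix selecting voxels (default: the map's cell
#'   mask, or everything).
#' @param regions Optional integer label matrix (0 = unlabeled).
#' @return A list with `total_mass` (pg) and, when `regions` is given,
#'   `per_region_mass` (named numeric, pg). An empty ROI yields mass 0
#'   with a warning.
#' @export
integrate_mass <- function(map, roi = NULL, regions = NULL) {
  stopifnot(inherits(map, "drymass_map"))
  if (is.null(roi)) roi <- if (!is.null(map$cell_mask)) map$cell_mask else
    array(TRUE, dim(map$density_map))
  if (!identical(dim(roi), dim(map$density_map)))
    stop("'roi' must match the density map dimensions")
  vox <- map$voxel_area * map$slice_thickness
  if (!any(roi)) {
    warning("empty region of interest: mass is 0")
    return(list(total_mass = 0))
  }
  out <- list(total_mass = sum(map$density_map[roi]) * vox)
  if (!is.null(regions)) {
    labs <- sort(unique(regions[roi & regions > 0]))
    out$per_region_mass <- vapply(labs, function(l)
      sum(map$density_map[roi & regions == l]) * vox, numeric(1))
    names(out$per_region_mass) <- as.character(labs)
  }
  out
}

#' Per-pixel column mass from a recovered z-stack
#'
#' Sums density over co-registered slices for each pixel,
#' `mass(x, y) = sum_k rho(x, y, k) * voxel_area * slice_thickness`,
#' restricted to voxels flagged as sample (contrast magnitude above the
#' noise floor). Intended for stacks whose slices tile distinct axial
#' slabs; for focus-scanned stacks of a single slab use the in-focus slice
#' with [field_density()] instead.
#'
#' @param fields List of `recovered_field` objects, identical geometry.
#' @param slice_thickness Axial extent of one slice (um).
#' @param noise_floor Contrast gate for sample voxels; default from the
#'   first field.
#' @return Matrix of per-pixel mass (pg).
#' @export
column_mass <- function(fields, slice_thickness,
                        noise_floor = fields[[1L]]$noise_floor) {
  if (length(fields) == 0L) stop("no slices")
  dims <- lapply(fields, function(f) dim(f$delta_n_map))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("inconsistent slice geometry")
  pp <- fields[[1L]]$pixel_pitch
  acc <- matrix(0, dims[[1L]][1], dims[[1L]][2])
  for (f in fields) {
    rho <- gladstone_dale(f$ri_map, f$optics)
    keep <- abs(f$delta_n_map) > noise_floor
    acc <- acc + rho * keep
  }
  acc * pp^2 * slice_thickness
}
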