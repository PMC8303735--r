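#' Write an interferogram stack to multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered z outer, wavelength inner (the package's documented
#' convention for multichannel stacks). Intensities are stored as 32-bit
#' float after division by `intensity_scale` (recorded in the sidecar) so
#' that values fit the TIFF writer's unit range. The sidecar carries
#' `wavelengths_nm`, `z_positions_nm`, `pixel_pitch_um`, the calibration
#' (`background` values or `background_roi`), and the page ordering.
#'
#' @param stack An [interferogram_stack()].
#' @param tiff_path,sidecar_path Output paths.
#' @param intensity_scale Divisor applied before writing; default a power
#'   of two covering the data range.
#' @return Invisibly, the sidecar list.
#' @export
write_interferogram <- function(stack, tiff_path, sidecar_path,
                                intensity_scale = NULL) {
  stopifnot(inherits(stack, "interferogram_stack"))
  d <- dim(stack$images)
  if (is.null(intensity_scale))
    intensity_scale <- max(1, 2^ceiling(log2(max(stack$images, 1e-12))))
  pages <- list()
  for (z in seq_len(d[4]))
    for (l in seq_len(d[3]))
      pages[[length(pages) + 1L]] <-
        stack$images[, , l, z] / intensity_scale
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  sidecar <- list(wavelengths_nm = as.numeric(unclass(stack$wl)),
                  z_positions_nm = stack$z_positions,
                  pixel_pitch_um = stack$pixel_pitch,
                  intensity_scale = intensity_scale,
                  page_order = "z_outer_wavelength_inner")
  if (!is.null(stack$background))
    sidecar$background <- as.numeric(stack$background)
  if (!is.null(stack$background_roi))
    sidecar$background_roi <- as.integer(stack$background_roi)
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read an interferogram stack from TIFF plus sidecar
#'
#' @param tiff_path,sidecar_path Paths written by [write_interferogram()].
#' @return An [interferogram_stack()].
#' @export
read_interferogram <- function(tiff_path, sidecar_path) {
  if (!file.exists(sidecar_path))
    stop("sidecar not found: ", sidecar_path,
         " (wavelengths and z positions are required to interpret the TIFF)")
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  nl <- length(sc$wavelengths_nm)
  nz <- length(sc$z_positions_nm)
  if (length(pages) != nl * nz)
    stop(sprintf("TIFF has %d pages, sidecar implies %d (wavelengths x slices)",
                 length(pages), nl * nz))
  scl <- if (!is.null(sc$intensity_scale)) sc$intensity_scale else 1
  img <- array(0, c(dim(pages[[1L]]), nl, nz))
  p <- 1L
  for (z in seq_len(nz))
    for (l in seq_len(nl)) {
      img[, , l, z] <- pages[[p]] * scl
      p <- p + 1L
    }
  interferogram_stack(img, wl = wavelength_set(sc$wavelengths_nm),
                      z_positions = sc$z_positions_nm,
                      background = sc$background,
                      background_roi = sc$background_roi,
                      pixel_pitch = sc$pixel_pitch_um)
}

# write one float map as 32-bit TIFF with affine scaling into [0, 1];
# returns the scaling record for the provenance block
write_scaled_map <- function(map, path) {
  lo <- min(map); hi <- max(map)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((map - lo) / scale, path, bits.per.sample = 32L)
  list(file = basename(path), offset = lo, scale = scale)
}

#' Write recovered-field maps as TIFFs with a provenance record
#'
#' Writes the contrast, axial-offset, residual and RI maps as 32-bit
#' float TIFFs (each affinely scaled into the writer's unit range; the
#' offset/scale pairs are stored in the provenance JSON alongside the
#' grid, the optical constants and the package version).
#'
#' @param field A `recovered_field`.
#' @param prefix Output path prefix; files `<prefix>_<name>.tif` and
#'   `<prefix>_provenance.json` are created.
#' @param extra Optional named list merged into the provenance record
#'   (e.g. the seed of the simulation that produced the input).
#' @return Invisibly, the provenance list.
#' @export
write_field_maps <- function(field, prefix, extra = list()) {
  stopifnot(inherits(field, "recovered_field"))
  maps <- list(delta_n = field$delta_n_map, delta_z = field$delta_z_map,
               residual = field$residual_map, ri = field$ri_map)
  rec <- lapply(names(maps), function(nm)
    write_scaled_map(maps[[nm]], paste0(prefix, "_", nm, ".tif")))
  names(rec) <- names(maps)
  prov <- c(list(maps = rec,
                 grid = unclass(field$grid),
                 optics = unclass(field$optics),
                 slab_nm = field$slab,
                 z_position_nm = field$z_position,
                 pixel_pitch_um = field$pixel_pitch,
                 package_version = as.character(utils::packageVersion("mwii"))),
            extra)
  jsonlite::write_json(prov, paste0(prefix, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}

#' Write a per-cell record table as CSV
#'
#' Fixed column order as produced by [measure_cells()].
#'
#' @param records Data.frame of cell records.
#' @param path Output CSV path.
#' @export
write_cell_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
}
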