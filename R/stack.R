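#' Multichannel interferogram stack
#'
#' Container for a (possibly z-scanned) set of multichannel intensity
#' images. Images are stored as a 4-D array indexed
#' `[row, col, wavelength, z]`. The calibration reference is either an
#' explicit per-wavelength background intensity `T^2 U(lambda)^2`, or a
#' rectangular cell-free region from which it is estimated per wavelength
#' and slice as the median intensity.
#'
#' @param images Numeric 4-D array `[row, col, wavelength, z]` (a 3-D array
#'   is promoted to a single z-slice), all values non-negative.
#' @param wl A [wavelength_set()]; length must match `dim(images)[3]`.
#' @param z_positions Axial positions of the slices (nm), strictly
#'   increasing; length must match `dim(images)[4]`.
#' @param background Optional numeric vector, one reference intensity per
#'   wavelength.
#' @param background_roi Optional integer vector `c(row1, row2, col1, col2)`
#'   declaring a cell-free rectangle used to estimate the background.
#' @param pixel_pitch Lateral size of one pixel at the sample plane (um).
#'   Default 16/60 um (EMCCD pixel over 60x magnification).
#' @return An object of class `interferogram_stack`.
#' @export
interferogram_stack <- function(images, wl = wavelength_set(),
                                z_positions = 0, background = NULL,
                                background_roi = NULL,
                                pixel_pitch = 16 / 60) {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 4L)
    stop("'images' must be a [row, col, wavelength, z] array")
  if (any(images < 0)) stop("intensities must be non-negative")
  if (dim(images)[3] != length(wl))
    stop("third array dimension must match the wavelength set")
  z_positions <- as.numeric(z_positions)
  if (dim(images)[4] != length(z_positions))
    stop("fourth array dimension must match 'z_positions'")
  if (length(z_positions) > 1L && any(diff(z_positions) <= 0))
    stop("'z_positions' must be strictly increasing")
  if (!is.null(background) && length(background) != length(wl))
    stop("'background' needs one value per wavelength")
  if (is.null(background) && is.null(background_roi))
    stop("either 'background' or 'background_roi' is required for calibration")
  if (!is.null(background_roi)) {
    background_roi <- as.integer(background_roi)
    if (length(background_roi) != 4L ||
        background_roi[1] < 1L || background_roi[2] > dim(images)[1] ||
        background_roi[3] < 1L || background_roi[4] > dim(images)[2] ||
        background_roi[1] > background_roi[2] ||
        background_roi[3] > background_roi[4])
      stop("'background_roi' must be c(row1, row2, col1, col2) within the image")
  }
  if (pixel_pitch <= 0) stop("'pixel_pitch' must be positive (um)")
  structure(list(images = images, wl = wl, z_positions = z_positions,
                 background = background, background_roi = background_roi,
                 pixel_pitch = pixel_pitch),
            class = "interferogram_stack")
}

#' @export
print.interferogram_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<interferogram_stack> %d x %d px, %d wavelengths (%s nm), %d z-slice(s)\n",
              d[1], d[2], d[3], paste(unclass(x$wl), collapse = "/"), d[4]))
  invisible(x)
}

#' Background reference intensities of a stack
#'
#' Returns the per-wavelength reference intensity `T^2 U(lambda)^2` for one
#' z-slice: the explicit calibration values if present, otherwise the
#' median intensity over the declared cell-free region.
#'
#' @param stack An [interferogram_stack()].
#' @param z_index Slice index (used only for ROI-based estimation).
#' @return Numeric vector, one value per wavelength.
#' @export
stack_background <- function(stack, z_index = 1L) {
  stopifnot(inherits(stack, "interferogram_stack"))
  if (!is.null(stack$background)) return(as.numeric(stack$background))
  r <- stack$background_roi
  vapply(seq_along(stack$wl), function(l)
    stats::median(stack$images[r[1]:r[2], r[3]:r[4], l, z_index]),
    numeric(1))
}

#' Normalized intensities of one slice
#'
#' Divides the raw intensities of slice `z_index` by the per-wavelength
#' background reference, yielding the calibration-free quantity
#' `Ihat = I / (T^2 U^2)` that the inversion fits.
#'
#' @inheritParams stack_background
#' @return A 3-D array `[row, col, wavelength]` of normalized intensities.
#' @export
normalized_slice <- function(stack, z_index = 1L) {
  bg <- stack_background(stack, z_index)
  if (any(bg <= 0)) stop("background reference must be positive; check calibration")
  sl <- stack$images[, , , z_index, drop = FALSE]
  dim(sl) <- dim(stack$images)[1:3]
  sweep(sl, 3L, bg, "/")
}
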