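#' Threshold a refractive-index map at the nucleus cutoff
#'
#' Nuclear chromatin is denser than cytoplasm; in this convention its RI
#' exceeds 1.42, which is the default segmentation threshold. The
#' inequality is strict: a pixel exactly at the threshold is excluded.
#'
#' @param ri_map Numeric matrix of refractive indices (finite).
#' @param threshold RI cutoff, default 1.42.
#' @return Boolean matrix.
#' @export
threshold_nucleus <- function(ri_map, threshold = 1.42) {
  if (any(!is.finite(ri_map))) stop("'ri_map' must be finite")
  ri_map > threshold
}

# disk structuring element with the given pixel radius
disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Morphological cleaning of a binary mask
#'
#' Erosion with a disk structuring element followed by removal of small
#' connected components (8-connectivity), the standard recipe for
#' suppressing isolated supra-threshold speckles.
#'
#' @param mask Boolean matrix.
#' @param erosion_radius Disk radius in px (default 2); 0 skips erosion.
#' @param min_size Minimum component size in px kept after erosion
#'   (default 20).
#' @return Boolean matrix.
#' @export
clean_mask <- function(mask, erosion_radius = 2, min_size = 20) {
  m <- mask * 1
  if (!any(m > 0)) return(mask & FALSE)
  if (erosion_radius > 0)
    m <- EBImage::erode(m, disk_brush(erosion_radius))
  if (min_size > 0 && any(m > 0)) {
    lab <- EBImage::bwlabel(m)
    sz <- tabulate(lab[lab > 0])
    keep <- which(sz >= min_size)
    m <- matrix(lab %in% keep, nrow(mask), ncol(mask)) * 1
  }
  m > 0
}

# Sobel gradients of a matrix: gc along columns, gr along rows
sobel_gradients <- function(x) {
  kc <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  list(gc = EBImage::filter2(x, kc), gr = EBImage::filter2(x, t(kc)))
}

#' Canny edge detection on a refractive-index map
#'
#' Gaussian smoothing, Sobel gradients, plateau-preserving non-maximum
#' suppression (a pixel survives when its gradient magnitude is not
#' exceeded by either neighbour along the gradient direction, so the
#' two-pixel-wide ridges of sharp discrete steps are kept whole), and
#' hysteresis thresholding. Hysteresis levels are automatic: `high` is the
#' given quantile of the gradient magnitude within the region of interest,
#' `low` is half of it.
#'
#' @param img Numeric matrix.
#' @param roi Optional boolean matrix restricting both the quantile
#'   estimate and the reported edges.
#' @param sigma Gaussian pre-smoothing sd in px.
#' @param high_quantile Quantile of the in-ROI gradient magnitude that
#'   sets the strong-edge threshold.
#' @return Boolean edge map.
#' @export
canny_edges <- function(img, roi = NULL, sigma = 1, high_quantile = 0.9) {
  sm <- EBImage::gblur(img, sigma = sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gc^2 + g$gr^2)
  if (is.null(roi)) roi <- array(TRUE, dim(img))
  if (!any(roi) || all(mag[roi] == 0)) return(array(FALSE, dim(img)))
  # non-maximum suppression along the quantized gradient direction
  nr <- nrow(img); nc <- ncol(img)
  ang <- atan2(g$gr, g$gc)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:+col 1:diag 2:+row 3:anti-diag
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  shift_mat <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    r_src <- max(1L, 1L - dr):min(nr, nr - dr)
    c_src <- max(1L, 1L - dc):min(nc, nc - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  keep <- array(FALSE, dim(img))
  for (s in 0:3) {
    d <- off[[s + 1L]]
    fwd <- shift_mat(mag, d[1], d[2])
    bwd <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= fwd & mag >= bwd)
  }
  high <- stats::quantile(mag[roi], high_quantile, names = FALSE)
  low <- high / 2
  if (high <= 0) return(array(FALSE, dim(img)))
  strong <- keep & roi & mag >= high
  weak <- keep & roi & mag >= low
  if (!any(strong)) return(array(FALSE, dim(img)))
  lab <- EBImage::bwlabel(weak * 1)
  good <- unique(lab[strong])
  matrix(lab %in% good[good > 0], nr, nc)
}

#' Refine a cleaned nucleus mask using edge geometry
#'
#' Recovers nucleus pixels that fall below the RI threshold (chromatin is
#' textured, so interior holes are common): edges of the nuclear boundary
#' are detected on the RI map with [canny_edges()] in a neighbourhood of
#' the mask, the contour is closed robustly (edges dilated by the bridge
#' radius, hull filled, then eroded back, which tolerates small gaps in
#' the detected ring), and the final mask unites the connected interior
#' components that touch the dilated input mask with the supra-threshold
#' pixels enclosed by the contour. If no closed contour is found the
#' cleaned input is returned unchanged with a warning.
#'
#' @param mask Cleaned binary nucleus mask (see [clean_mask()]).
#' @param ri_map Refractive-index map the mask was derived from.
#' @param dilation_radius Disk radius (px) of the compensating dilation.
#' @param threshold RI threshold used for the supra-threshold rescue.
#' @param sigma,high_quantile Passed to [canny_edges()].
#' @param bridge_radius Disk radius (px) used to bridge gaps in the edge
#'   contour before hull filling.
#' @return Boolean nucleus mask.
#' @export
refine_nucleus <- function(mask, ri_map, dilation_radius = 3,
                           threshold = 1.42, sigma = 1,
                           high_quantile = 0.9, bridge_radius = 2) {
  if (!any(mask)) return(mask)
  neigh <- EBImage::dilate(mask * 1, disk_brush(dilation_radius + 2)) > 0
  edges <- canny_edges(ri_map, roi = neigh, sigma = sigma,
                       high_quantile = high_quantile)
  if (!any(edges)) {
    warning("no edges found near the mask; keeping the cleaned mask")
    return(mask)
  }
  bb <- disk_brush(bridge_radius)
  filled <- EBImage::fillHull(EBImage::dilate(edges * 1, bb)) > 0
  enclosed <- EBImage::erode(filled * 1, bb) > 0
  interior <- enclosed & !edges
  if (!any(interior)) {
    warning("edge contour does not close; keeping the cleaned mask")
    return(mask)
  }
  dilated <- EBImage::dilate(mask * 1, disk_brush(dilation_radius)) > 0
  # keep whole interior components that touch the dilated input mask, so
  # sub-threshold holes deep inside the nucleus are recovered even when
  # the cleaning erosion has carved a wide moat around them
  lab <- EBImage::bwlabel(interior * 1)
  keep <- unique(lab[lab > 0 & dilated])
  inside <- matrix(lab %in% keep, nrow(mask), ncol(mask)) & interior
  out <- inside | (threshold_nucleus(ri_map, threshold) & enclosed)
  if (!any(out)) {
    warning("refinement produced an empty mask; keeping the cleaned mask")
    return(mask)
  }
  out
}

#' Cell-support mask from a recovered field
#'
#' Pixels whose recovered contrast magnitude exceeds the noise floor,
#' cleaned by small-component removal and hole filling. Erosion is
#' deliberately not applied here: shaving the cell boundary would bias
#' total dry mass low, whereas isolated background speckles and interior
#' dropouts (pixels whose RI happens to sit near the carrier index) are
#' what actually needs correcting.
#'
#' @param field A `recovered_field`.
#' @param noise_floor Contrast gate, default the field's.
#' @param min_size Minimum component size in px.
#' @return Boolean matrix.
#' @export
cell_support <- function(field, noise_floor = field$noise_floor,
                         min_size = 20) {
  m <- sample_mask(field, noise_floor)
  m <- clean_mask(m, erosion_radius = 0, min_size = min_size)
  if (any(m)) m <- EBImage::fillHull(m * 1) > 0
  m
}

#' Nucleus / cytoplasm / cell mask triple
#'
#' Builds the partition used for compartmental dry mass: cytoplasm is the
#' cell support minus the nucleus. A nucleus extending outside the cell is
#' clipped with a warning. The invariants (nucleus and cytoplasm disjoint,
#' their union the cell mask, nucleus inside the cell) hold for every
#' output.
#'
#' @param nucleus_mask,cell_mask Boolean matrices of equal dimension.
#' @param params Optional list of the parameters that produced the masks,
#'   stored for provenance.
#' @return An object of class `segmentation_mask` with elements
#'   `nucleus_mask`, `cytoplasm_mask`, `cell_mask`, `params`.
#' @export
decompose_masks <- function(nucleus_mask, cell_mask, params = list()) {
  if (!identical(dim(nucleus_mask), dim(cell_mask)))
    stop("mask dimensions differ")
  if (any(nucleus_mask & !cell_mask)) {
    warning("nucleus extends outside the cell mask; clipping")
    nucleus_mask <- nucleus_mask & cell_mask
  }
  structure(list(nucleus_mask = nucleus_mask,
                 cytoplasm_mask = cell_mask & !nucleus_mask,
                 cell_mask = cell_mask, params = params),
            class = "segmentation_mask")
}

#' Full nucleus segmentation of a refractive-index map
#'
#' The standard pipeline: RI threshold, morphological cleaning, and
#' edge-guided refinement, combined with the cell support into a
#' [decompose_masks()] partition.
#'
#' @param field A `recovered_field`.
#' @param threshold Nucleus RI threshold.
#' @param erosion_radius,min_size Cleaning parameters, see [clean_mask()].
#' @param dilation_radius Refinement dilation radius.
#' @param cell_mask Optional externally supplied cell mask; default
#'   [cell_support()].
#' @return A `segmentation_mask`.
#' @export
segment_nucleus <- function(field, threshold = 1.42, erosion_radius = 2,
                            min_size = 20, dilation_radius = 3,
                            cell_mask = NULL) {
  stopifnot(inherits(field, "recovered_field"))
  if (is.null(cell_mask)) cell_mask <- cell_support(field)
  raw <- threshold_nucleus(field$ri_map, threshold)
  cleaned <- clean_mask(raw, erosion_radius, min_size)
  nuc <- if (any(cleaned))
    refine_nucleus(cleaned, field$ri_map, dilation_radius, threshold)
  else cleaned
  decompose_masks(nuc, cell_mask,
                  params = list(threshold = threshold,
                                erosion_radius = erosion_radius,
                                min_size = min_size,
                                dilation_radius = dilation_radius))
}
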