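#' Optical constants of the layered imaging scene
#'
#' Bundle the refractive indices and the specific refractive increment that
#' define the medium / sample / substrate stack seen by the interferometric
#' forward model. The sample refractive index is parameterised as
#' `n = n1 * (1 + dn(z))`, i.e. `n1` is the carrier (mean) index and `dn`
#' the dimensionless fluctuation about it.
#'
#' @param n0 Refractive index of the immersion medium (culture medium,
#'   water, or air). Dimensionless.
#' @param n1 Mean refractive index of the sample; cytoplasm averages about
#'   1.36 in the QPI literature, which is the default.
#' @param n2 Refractive index of the substrate (glass coverslip by default).
#' @param nw Refractive index of water, the baseline of the Gladstone-Dale
#'   relation.
#' @param alpha Specific refractive increment in mL/g; near 0.18 mL/g for
#'   the mixture of biomolecules making up cellular dry mass.
#'
#' @return An object of class `optical_stack` (a named list).
#' @examples
#' optics <- optical_stack()
#' fresnel_prefactor(optics)
#' @export
optical_stack <- function(n0 = 1.337, n1 = 1.36, n2 = 1.52,
                          nw = 1.333, alpha = 0.18) {
  for (nm in c("n0", "n1", "n2", "nw")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 || v >= 5)
      stop(sprintf("'%s' must be a single refractive index in [1, 5)", nm))
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive specific refractive increment (mL/g)")
  structure(list(n0 = n0, n1 = n1, n2 = n2, nw = nw, alpha = alpha),
            class = "optical_stack")
}

#' @export
print.optical_stack <- function(x, ...) {
  cat("<optical_stack> n0 =", x$n0, " n1 =", x$n1, " n2 =", x$n2,
      " nw =", x$nw, " alpha =", x$alpha, "mL/g\n")
  invisible(x)
}

#' Illumination wavelength set
#'
#' The vacuum wavelengths of the multichannel illumination, in nm. The
#' instrument default is the four-filter set 447, 525, 593, 692 nm; at
#' least two wavelengths are required for the joint (dn, dz) inversion.
#'
#' @param lambdas Numeric vector of vacuum wavelengths (nm), strictly
#'   positive.
#' @return A numeric vector of class `wavelength_set`.
#' @export
wavelength_set <- function(lambdas = c(447, 525, 593, 692)) {
  if (!is.numeric(lambdas) || length(lambdas) < 1L || any(!is.finite(lambdas)) ||
      any(lambdas <= 0))
    stop("'lambdas' must be positive wavelengths in nm")
  structure(as.numeric(lambdas), class = "wavelength_set")
}

#' Axial contrast profile of one image column
#'
#' Describes the refractive-index fluctuation dn(z) along the optical axis
#' for one lateral position, sampled on a strictly increasing axial grid
#' (nm, measured from the substrate). `delta_z` is the unknown nanoscale
#' correction of the recorded focal-plane position that the inversion
#' recovers alongside the contrast.
#'
#' @param z_grid Axial sample coordinates (nm), strictly increasing.
#' @param delta_n Contrast dn(z) at each coordinate; must lie in
#'   \[-0.5, 0.5\] (weak-scattering regime).
#' @param delta_z Focal-plane modification (nm).
#' @return An object of class `axial_profile`.
#' @seealso [slab_profile()] for the uniform-slab special case.
#' @export
axial_profile <- function(z_grid, delta_n, delta_z = 0) {
  z_grid <- as.numeric(z_grid); delta_n <- as.numeric(delta_n)
  if (length(z_grid) != length(delta_n))
    stop("'z_grid' and 'delta_n' must have the same length")
  if (length(z_grid) > 1L && any(diff(z_grid) <= 0))
    stop("'z_grid' must be strictly increasing")
  if (any(!is.finite(delta_n)) || any(abs(delta_n) > 0.5))
    stop("'delta_n' must be finite and within [-0.5, 0.5]")
  structure(list(z_grid = z_grid, delta_n = delta_n,
                 delta_z = as.numeric(delta_z)),
            class = "axial_profile")
}

#' Uniform slab profile
#'
#' Convenience constructor for a slab of constant contrast `dn` occupying
#' `[a, b]` nm, sampled densely enough for accurate quadrature. The default
#' sampling places 2000 points per oscillation period of the scattering
#' integrand (period `lambda / (2 n1)`), at which the trapezoidal rule
#' matches the closed form to better than 1e-6 relative error.
#'
#' @param a,b Slab boundaries (nm), `a < b`.
#' @param dn Constant contrast inside the slab.
#' @param delta_z Focal-plane modification (nm).
#' @param n1 Carrier refractive index (sets the integrand period).
#' @param lambda_min Shortest wavelength to be used (nm); controls sampling.
#' @param samples_per_period Sampling density of the axial grid.
#' @return An `axial_profile`.
#' @export
slab_profile <- function(a, b, dn, delta_z = 0, n1 = 1.36,
                         lambda_min = 447, samples_per_period = 2000) {
  if (!(a < b)) stop("slab requires a < b")
  period <- lambda_min / (2 * n1)
  n_pts <- max(16L, ceiling((b - a) / period * samples_per_period) + 1L)
  z <- seq(a, b, length.out = n_pts)
  axial_profile(z, rep(dn, n_pts), delta_z = delta_z)
}

#' Fresnel transmission prefactor of the reference beam
#'
#' The scalar factor `T = 4 n0 n1 / ((n0 + n1)(n1 + n2))` by which the
#' illumination amplitude is scaled on its way through the
#' medium/sample/substrate stack. Both the reference and the scattered
#' field carry this factor, so it cancels from normalized intensities.
#'
#' @param stack An [optical_stack()].
#' @return The dimensionless prefactor (a scalar in (0, 1.1] for physical
#'   index combinations).
#' @examples
#' fresnel_prefactor(optical_stack(n0 = 1, n1 = 1.36, n2 = 1.52))
#' @export
fresnel_prefactor <- function(stack) {
  stopifnot(inherits(stack, "optical_stack"))
  4 * stack$n0 * stack$n1 / ((stack$n0 + stack$n1) * (stack$n1 + stack$n2))
}

#' Axial scattering integral
#'
#' Evaluates `S(lambda) = integral dn(z) sin(4 pi n1 (z + dz) / lambda) dz`
#' over the axial profile by trapezoidal quadrature (result in nm). This is
#' the quantity that modulates the interference term of the coherent
#' intensity; for a uniform slab it has the closed form returned by
#' [slab_scattering_integral()].
#'
#' @param profile An [axial_profile()].
#' @param stack An [optical_stack()] supplying the carrier index `n1`.
#' @param lambda Vacuum wavelength (nm), scalar.
#' @return `S(lambda)` in nm.
#' @details The axial grid must sample the integrand with at least 20
#'   points per oscillation period `lambda / (2 n1)`; coarser grids raise
#'   an error rather than silently aliasing.
#' @export
scattering_integral <- function(profile, stack, lambda) {
  stopifnot(inherits(profile, "axial_profile"), inherits(stack, "optical_stack"))
  z <- profile$z_grid
  if (length(z) < 2L) return(0)
  period <- lambda / (2 * stack$n1)
  if (max(diff(z)) > period / 20)
    stop(sprintf(
      "axial grid undersampled: max spacing %.3g nm exceeds %.3g nm (period/20) at lambda = %g nm",
      max(diff(z)), period / 20, lambda))
  k <- 4 * pi * stack$n1 / lambda
  integrand <- profile$delta_n * sin(k * (z + profile$delta_z))
  sum((integrand[-1] + integrand[-length(z)]) / 2 * diff(z))
}

#' Closed-form scattering integral of a uniform slab
#'
#' For a slab of constant contrast `dn` on `[a, b]` the scattering integral
#' evaluates analytically to
#' `dn * lambda / (4 pi n1) * (cos(k (a + dz)) - cos(k (b + dz)))` with
#' `k = 4 pi n1 / lambda`. Used as the forward model of the grid-search
#' inversion and as the oracle for the quadrature path.
#'
#' @param a,b Slab boundaries (nm).
#' @param dn Constant contrast.
#' @param delta_z Focal-plane modification (nm).
#' @param n1 Carrier refractive index.
#' @param lambda Vacuum wavelength(s) (nm); vectorised.
#' @return `S(lambda)` in nm, same length as `lambda`.
#' @export
slab_scattering_integral <- function(a, b, dn, delta_z, n1, lambda) {
  k <- 4 * pi * n1 / lambda
  dn * lambda / (4 * pi * n1) * (cos(k * (a + delta_z)) - cos(k * (b + delta_z)))
}

#' Coherent intensity at the image plane
#'
#' Computes the interference intensity of the reference beam with the field
#' scattered by axial refractive-index fluctuations,
#' `I(lambda) = T^2 U^2 + 2 T^2 (2 pi n1 / lambda) S(lambda) U^2`,
#' dropping the quadratic scattered-field term (weak-scattering
#' approximation). Also returns the calibration-free normalized intensity
#' `Ihat = I / (T^2 U^2) = 1 + (4 pi n1 / lambda) S(lambda)`.
#'
#' @param profile An [axial_profile()] (or `NULL` for an empty column,
#'   giving the pure reference beam).
#' @param stack An [optical_stack()].
#' @param wl A [wavelength_set()].
#' @param U Illumination field amplitude per wavelength (arbitrary units);
#'   recycled to the number of wavelengths. Must be non-negative.
#' @return A data.frame with columns `lambda`, `intensity`, `normalized`.
#'   A warning is emitted if any normalized intensity is negative, which
#'   signals a violation of the weak-scattering assumption.
#' @examples
#' co <- coherent_intensity(slab_profile(0, 500, 0.05), optical_stack(),
#'                          wavelength_set(), U = 1)
#' co$normalized
#' @export
coherent_intensity <- function(profile, stack, wl = wavelength_set(), U = 1) {
  stopifnot(inherits(stack, "optical_stack"), inherits(wl, "wavelength_set"))
  U <- rep_len(as.numeric(U), length(wl))
  if (any(U < 0)) stop("illumination amplitudes must be non-negative")
  Tt <- fresnel_prefactor(stack)
  S <- if (is.null(profile)) rep(0, length(wl)) else
    vapply(unclass(wl), function(l) scattering_integral(profile, stack, l),
           numeric(1))
  ihat <- 1 + (4 * pi * stack$n1 / unclass(wl)) * S
  if (any(ihat < 0))
    warning("normalized intensity below zero: weak-scattering assumption violated")
  data.frame(lambda = unclass(wl),
             intensity = Tt^2 * U^2 * ihat,
             normalized = ihat)
}

#' Normalized slab intensity (vectorised forward model)
#'
#' Fast closed-form normalized intensity of a uniform slab,
#' `Ihat(lambda) = 1 + dn * (cos(k (a + dz)) - cos(k (b + dz)))`,
#' `k = 4 pi n1 / lambda`. This is the model the grid-search inversion
#' fits; `dn` and `delta_z` may be vectors (recycled together).
#'
#' @inheritParams slab_scattering_integral
#' @param lambda Vacuum wavelength (nm), scalar here.
#' @return Normalized intensities, same length as `dn`/`delta_z`.
#' @export
slab_normalized_intensity <- function(a, b, dn, delta_z, n1, lambda) {
  k <- 4 * pi * n1 / lambda
  1 + dn * (cos(k * (a + delta_z)) - cos(k * (b + delta_z)))
}
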