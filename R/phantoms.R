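#' @name phantoms
#' @title Synthetic phantom generators
#' @description
#' Every analysis stage of the package is testable without hardware: the
#' generators below build wafer, microsphere, cell, osmotic-shock and
#' growth-series phantoms through the same forward model the inversion
#' fits, carry machine-readable ground truth, and are bit-reproducible
#' given a seed.
NULL

# wavelength-dependent Gaussian defocus attenuation of the scattering term
defocus_envelope <- function(dz_eff, lambda, na = 0.7) {
  exp(-0.5 * (pi * na^2 * dz_eff / lambda)^2)
}

# raw intensity slice from a contrast map over slab [a, b] at effective
# focal offset dz_eff; returns [row, col, wavelength]
phantom_slice <- function(dn_map, a, b, dz_eff, optics, wl, U = 1,
                          envelope = FALSE, na = 0.7) {
  lam <- as.numeric(unclass(wl))
  Tt <- fresnel_prefactor(optics)
  bg <- Tt^2 * rep_len(U, length(lam))^2
  out <- array(0, c(dim(dn_map), length(lam)))
  for (l in seq_along(lam)) {
    k <- 4 * pi * optics$n1 / lam[l]
    C <- cos(k * (a + dz_eff)) - cos(k * (b + dz_eff))
    if (envelope) C <- C * defocus_envelope(dz_eff, lam[l], na)
    out[, , l] <- bg[l] * (1 + dn_map * C)
  }
  out
}

# detector-like noise on raw intensities
apply_noise <- function(images, model = c("none", "gaussian_additive",
                                          "multiplicative"), sd = 0) {
  model <- match.arg(model)
  if (model == "none" || sd == 0) return(images)
  eps <- array(stats::rnorm(length(images), 0, sd), dim(images))
  out <- switch(model,
                gaussian_additive = images + eps,
                multiplicative = images * (1 + eps))
  pmax(out, 0)
}

#' Default optical constants for wafer-mode phantoms
#'
#' Silica layer (carrier index 1.45) in air on a silicon substrate. The
#' substrate index never reaches normalized intensities (the Fresnel
#' prefactor cancels).
#' @return An [optical_stack()].
#' @export
wafer_optics <- function() optical_stack(n0 = 1.0, n1 = 1.45, n2 = 3.88)

#' Simulate a uniform layer ("wafer") interferogram
#'
#' A slab of known contrast (layer vs. ambient, in the model's fractional
#' convention) and given thickness, imaged at the four default wavelengths.
#'
#' @param thickness Layer thickness (nm).
#' @param delta_z True focal-plane offset (nm).
#' @param optics An [optical_stack()]; default [wafer_optics()].
#' @param wl A [wavelength_set()].
#' @param shape Image dimensions in px.
#' @param noise,noise_sd Noise model and amplitude (fraction of intensity
#'   for `"multiplicative"`).
#' @param seed Optional RNG seed (recorded in the ground truth).
#' @return A list with `stack` (an [interferogram_stack()]) and `truth`
#'   (thickness, layer contrast, delta_z, seed).
#' @export
make_wafer <- function(thickness, delta_z = 0, optics = wafer_optics(),
                       wl = wavelength_set(), shape = c(8, 8),
                       noise = "none", noise_sd = 0, seed = NULL) {
  if (thickness < 0) stop("'thickness' must be non-negative (nm)")
  if (!is.null(seed)) set.seed(seed)
  dn_layer <- (optics$n1 - optics$n0) / optics$n1
  dn_map <- matrix(if (thickness > 0) dn_layer else 0, shape[1], shape[2])
  b <- if (thickness > 0) thickness else 1  # degenerate slab: no contrast anyway
  img <- phantom_slice(dn_map, 0, b, delta_z, optics, wl)
  img <- apply_noise(img, noise, noise_sd)
  Tt <- fresnel_prefactor(optics)
  stack <- interferogram_stack(img, wl = wl, z_positions = 0,
                               background = rep(Tt^2, length(wl)))
  list(stack = stack,
       truth = list(kind = "wafer", thickness = thickness,
                    dn_layer = dn_layer, delta_z = delta_z, seed = seed))
}

#' Simulate a field of microspheres
#'
#' Spheres of one material are placed at non-overlapping, seeded pixel
#' centres; each sphere's true refractive index is drawn uniformly within
#' `ri_jitter` of the nominal value (off any inversion grid by
#' construction). The carrier index `n1` is the nominal material RI, so
#' per-sphere contrast is the small fractional deviation
#' `(RI_true - n1) / n1`; the central-pixel chord equals the diameter.
#'
#' @param material_ri Nominal refractive index of the material.
#' @param n_spheres Number of spheres.
#' @param diameter Sphere diameter (nm).
#' @param ri_jitter Half-width of the uniform true-RI jitter.
#' @param medium_ri Immersion medium index.
#' @param shape Image dimensions (px).
#' @param pixel_pitch Lateral pixel size (um).
#' @param delta_z True focal offset (nm).
#' @param noise,noise_sd Noise model and amplitude.
#' @param seed RNG seed.
#' @param max_retries Placement retries before giving up.
#' @return A list with `stack`, `optics`, and `truth` (per-sphere centres,
#'   true RI, contrast; the diameter; the seed).
#' @export
make_microsphere_field <- function(material_ri = 1.59, n_spheres = 20,
                                   diameter = 500, ri_jitter = 0.002,
                                   medium_ri = 1.333, shape = c(64, 64),
                                   pixel_pitch = 16 / 60, delta_z = 0,
                                   noise = "none", noise_sd = 0,
                                   seed = NULL, max_retries = 2000) {
  if (!is.null(seed)) set.seed(seed)
  if (diameter <= 0) stop("'diameter' must be positive (nm)")
  optics <- optical_stack(n0 = medium_ri, n1 = material_ri, n2 = 1.52)
  # minimal centre separation so footprints never touch
  sep_px <- ceiling(diameter / (pixel_pitch * 1000)) + 1L
  margin <- sep_px + 1L
  centres <- matrix(NA_integer_, 0, 2)
  tries <- 0L
  while (nrow(centres) < n_spheres) {
    cand <- c(sample(margin:(shape[1] - margin), 1L),
              sample(margin:(shape[2] - margin), 1L))
    ok <- nrow(centres) == 0L ||
      all(pmax(abs(centres[, 1] - cand[1]), abs(centres[, 2] - cand[2])) >= sep_px)
    if (ok) centres <- rbind(centres, cand)
    tries <- tries + 1L
    if (tries > max_retries) stop("could not place spheres without overlap")
  }
  ri_true <- material_ri + stats::runif(n_spheres, -ri_jitter, ri_jitter)
  dn_true <- (ri_true - material_ri) / material_ri
  dn_map <- matrix(0, shape[1], shape[2])
  dn_map[centres] <- dn_true
  wl <- wavelength_set()
  img <- phantom_slice(dn_map, 0, diameter, delta_z, optics, wl)
  img <- apply_noise(img, noise, noise_sd)
  Tt <- fresnel_prefactor(optics)
  stack <- interferogram_stack(img, wl = wl, z_positions = 0,
                               background = rep(Tt^2, length(wl)),
                               pixel_pitch = pixel_pitch)
  list(stack = stack, optics = optics,
       truth = list(kind = "microsphere", centres = centres,
                    ri_true = ri_true, dn_true = dn_true,
                    diameter = diameter, delta_z = delta_z, seed = seed))
}

# elliptical footprint mask on the pixel grid (um geometry)
ellipse_mask <- function(shape, centre_px, axes_um, pixel_pitch) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cl <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - centre_px[1]) * pixel_pitch / axes_um[1])^2 +
    ((cl - centre_px[2]) * pixel_pitch / axes_um[2])^2 <= 1
}

# textured per-pixel RI field for a cell footprint
cell_ri_field <- function(cell, nucleus, cyt_ri, nuc_ri, n1) {
  ri <- matrix(n1, nrow(cell), ncol(cell))
  ncyt <- sum(cell & !nucleus); nnuc <- sum(nucleus)
  ri[cell & !nucleus] <- stats::runif(ncyt, cyt_ri[1], cyt_ri[2])
  ri[nucleus] <- stats::runif(nnuc, nuc_ri[1], nuc_ri[2])
  ri
}

#' Simulate a single-cell interferogram z-stack
#'
#' A columnar ("pancake") cell phantom: elliptical cell and nucleus
#' footprints, constant column height, per-pixel uniform refractive index
#' drawn from the cytoplasm and nucleus texture ranges. The z-stack
#' emulates a focal scan; slices away from focus carry a
#' wavelength-dependent Gaussian attenuation of the scattering term so
#' that fit residuals genuinely identify the in-focus slice. Ground-truth
#' masses are computed from the generating RI field with the same
#' Gladstone-Dale constants the pipeline uses, both as a voxel sum and as
#' a continuous-geometry integral.
#'
#' @param axes Cell footprint semi-axes (um).
#' @param nucleus_fraction Nucleus semi-axes as a fraction of the cell's
#'   (0 disables the nucleus).
#' @param height Column height (um): the nominal slab extent.
#' @param cyt_ri,nuc_ri Texture ranges `c(lo, hi)` of cytoplasm and
#'   nucleus RI.
#' @param centre_px Footprint centre (px); default the image centre.
#' @param shape Image dimensions (px).
#' @param pixel_pitch Lateral pixel size (um).
#' @param z_spacing,z_total Focal scan spacing and span (nm).
#' @param focus_z True in-focus scan position (nm); defaults to the scan
#'   midpoint.
#' @param delta_z0 Additional true focal offset (nm) at the in-focus
#'   slice.
#' @param defocus Apply the defocus envelope (`TRUE` for z-stacks).
#' @param na Numerical aperture of the emulated objective.
#' @param optics An [optical_stack()].
#' @param noise,noise_sd Noise model and amplitude.
#' @param seed RNG seed.
#' @return A list with `stack`, `optics`, and `truth` (RI map, cell and
#'   nucleus masks, voxel and continuous masses in pg, focus slice index,
#'   geometry, seed).
#' @export
make_cell <- function(axes = c(5.5, 4.5), nucleus_fraction = 0.45,
                      height = 3, cyt_ri = c(1.355, 1.375),
                      nuc_ri = c(1.425, 1.445), centre_px = NULL,
                      shape = c(64, 64), pixel_pitch = 16 / 60,
                      z_spacing = 100, z_total = 5000, focus_z = NULL,
                      delta_z0 = 0, defocus = TRUE, na = 0.7,
                      optics = optical_stack(), noise = "none",
                      noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nucleus_fraction < 0 || nucleus_fraction >= 1)
    stop("'nucleus_fraction' must be in [0, 1)")
  if (is.null(centre_px)) centre_px <- (shape + 1) / 2
  cell <- ellipse_mask(shape, centre_px, axes, pixel_pitch)
  nucleus <- if (nucleus_fraction > 0)
    ellipse_mask(shape, centre_px, axes * nucleus_fraction, pixel_pitch)
  else cell & FALSE
  ri <- cell_ri_field(cell, nucleus, cyt_ri, nuc_ri, optics$n1)
  dn_map <- (ri - optics$n1) / optics$n1
  z_positions <- seq(0, z_total, by = z_spacing)
  if (is.null(focus_z)) focus_z <- z_positions[ceiling(length(z_positions) / 2)]
  wl <- wavelength_set()
  h_nm <- height * 1000
  img <- array(0, c(shape, length(wl), length(z_positions)))
  for (j in seq_along(z_positions)) {
    dz_eff <- focus_z - z_positions[j] + delta_z0
    img[, , , j] <- phantom_slice(dn_map, 0, h_nm, dz_eff, optics, wl,
                                  envelope = defocus, na = na)
  }
  img <- apply_noise(img, noise, noise_sd)
  Tt <- fresnel_prefactor(optics)
  stack <- interferogram_stack(img, wl = wl, z_positions = z_positions,
                               background = rep(Tt^2, length(wl)),
                               pixel_pitch = pixel_pitch)
  vox <- pixel_pitch^2 * height                      # um^3 -> pg at 1 g/mL
  rho <- (ri - optics$nw) / optics$alpha
  masses <- list(
    total = sum(rho[cell]) * vox,
    nuclear = sum(rho[nucleus]) * vox,
    cytoplasmic = sum(rho[cell & !nucleus]) * vox)
  # continuous-geometry counterpart: exact ellipse areas x expected density
  rho_cyt <- (mean(cyt_ri) - optics$nw) / optics$alpha
  rho_nuc <- (mean(nuc_ri) - optics$nw) / optics$alpha
  a_cell <- pi * axes[1] * axes[2]
  a_nuc <- a_cell * nucleus_fraction^2
  masses_continuous <- list(
    total = ((a_cell - a_nuc) * rho_cyt + a_nuc * rho_nuc) * height,
    nuclear = a_nuc * rho_nuc * height,
    cytoplasmic = (a_cell - a_nuc) * rho_cyt * height)
  list(stack = stack, optics = optics,
       truth = list(kind = "cell", ri_map = ri, cell_mask = cell,
                    nucleus_mask = nucleus, masses = masses,
                    masses_continuous = masses_continuous,
                    focus_index = which.min(abs(z_positions - focus_z)),
                    height = height, axes = axes,
                    nucleus_fraction = nucleus_fraction,
                    delta_z0 = delta_z0, seed = seed))
}

# rescale (n - nw) inside a mask so its integral matches a target
conserve_ri <- function(ri, mask, nw, target) {
  cur <- sum(ri[mask] - nw)
  if (cur <= 0) return(ri)
  ri[mask] <- nw + (ri[mask] - nw) * target / cur
  ri
}

#' Simulate an osmotic-shock time series
#'
#' Eleven timepoints emulating isotonic / hyperosmotic / recovery
#' perfusion: the cell footprint shrinks laterally at the hyperosmotic
#' steps while the integrated refractive-index excess `(n - nw)` of each
#' compartment is renormalised to its baseline value, so true dry mass is
#' conserved exactly by construction while the footprint changes by well
#' over 12 percent.
#'
#' @param scales Footprint scale per timepoint; default 1 at 0 and 10 min,
#'   0.93 during the hyperosmotic phase (a 13.5 percent area change).
#' @param axes Baseline cell semi-axes (um).
#' @param nucleus_fraction,height,cyt_ri,nuc_ri,shape,pixel_pitch,optics
#'   As in [make_cell()].
#' @param z_spacing Focal scan spacing (nm).
#' @param n_slices Number of scan slices per timepoint (kept small: the
#'   osmotic protocol images once per minute).
#' @param noise,noise_sd Noise model and amplitude.
#' @param seed RNG seed (per-timepoint textures derive from it).
#' @return A list with `phantoms` (list of [make_cell()]-style outputs)
#'   and `truth` (per-timepoint true masses, footprint pixel counts,
#'   scales, seed).
#' @export
make_osmotic_series <- function(scales = c(1, rep(0.93, 9), 1),
                                axes = c(4.8, 4.0), nucleus_fraction = 0.45,
                                height = 3, cyt_ri = c(1.355, 1.375),
                                nuc_ri = c(1.425, 1.445), shape = c(48, 48),
                                pixel_pitch = 16 / 60, z_spacing = 100,
                                n_slices = 5, optics = optical_stack(),
                                noise = "none", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centre_px <- (shape + 1) / 2
  wl <- wavelength_set()
  h_nm <- height * 1000
  z_positions <- seq(0, by = z_spacing, length.out = n_slices)
  focus_z <- z_positions[ceiling(n_slices / 2)]
  Tt <- fresnel_prefactor(optics)
  vox <- pixel_pitch^2 * height
  target_nuc <- NULL; target_cyt <- NULL
  phantoms <- vector("list", length(scales))
  truth_mass <- numeric(length(scales))
  truth_nuclear <- numeric(length(scales))
  truth_size <- integer(length(scales))
  for (t in seq_along(scales)) {
    s <- scales[t]
    cell <- ellipse_mask(shape, centre_px, axes * s, pixel_pitch)
    nucleus <- if (nucleus_fraction > 0)
      ellipse_mask(shape, centre_px, axes * s * nucleus_fraction, pixel_pitch)
    else cell & FALSE
    ri <- cell_ri_field(cell, nucleus, cyt_ri, nuc_ri, optics$n1)
    if (t == 1L) {
      target_nuc <- sum(ri[nucleus] - optics$nw)
      target_cyt <- sum(ri[cell & !nucleus] - optics$nw)
    } else {
      ri <- conserve_ri(ri, nucleus, optics$nw, target_nuc)
      ri <- conserve_ri(ri, cell & !nucleus, optics$nw, target_cyt)
    }
    dn_map <- (ri - optics$n1) / optics$n1
    img <- array(0, c(shape, length(wl), n_slices))
    for (j in seq_len(n_slices)) {
      dz_eff <- focus_z - z_positions[j]
      img[, , , j] <- phantom_slice(dn_map, 0, h_nm, dz_eff, optics, wl,
                                    envelope = n_slices > 1L)
    }
    img <- apply_noise(img, noise, noise_sd)
    stack <- interferogram_stack(img, wl = wl, z_positions = z_positions,
                                 background = rep(Tt^2, length(wl)),
                                 pixel_pitch = pixel_pitch)
    rho <- (ri - optics$nw) / optics$alpha
    truth_mass[t] <- sum(rho[cell]) * vox
    truth_nuclear[t] <- sum(rho[nucleus]) * vox
    truth_size[t] <- sum(cell)
    phantoms[[t]] <- list(stack = stack, optics = optics,
                          truth = list(kind = "cell", ri_map = ri,
                                       cell_mask = cell,
                                       nucleus_mask = nucleus,
                                       height = height))
  }
  list(phantoms = phantoms,
       truth = list(kind = "osmotic_series", scales = scales,
                    total_mass = truth_mass, nuclear_mass = truth_nuclear,
                    size_px = truth_size, height = height, seed = seed))
}

#' Simulate a growth time-lapse with a scripted two-phase mass trajectory
#'
#' The true total dry mass follows a piecewise-linear two-phase curve:
#' within each phase the fractional change `(end - start) / start` equals
#' the scripted rate. Mass is modulated by scaling the refractive-index
#' excess of the whole cell; footprint and height stay fixed.
#'
#' @param rates Scripted `c(phase1, phase2)` fractional growth rates.
#' @param n_t Number of timepoints.
#' @param boundary_index Timepoint index at which phase 1 ends.
#' @param timestep Hours between timepoints.
#' @param axes,nucleus_fraction,height,cyt_ri,nuc_ri,shape,pixel_pitch,optics
#'   As in [make_cell()].
#' @param n_slices Scan slices per timepoint.
#' @param z_spacing Focal scan spacing (nm).
#' @param noise,noise_sd Noise model and amplitude.
#' @param seed RNG seed.
#' @return A list with `phantoms`, `truth` (scripted mass series,
#'   timepoints in h, boundary index, rates, seed).
#' @export
make_growth_series <- function(rates = c(0.053, 0.197), n_t = 12,
                               boundary_index = 7, timestep = 2,
                               axes = c(4.8, 4.0), nucleus_fraction = 0.45,
                               height = 3, cyt_ri = c(1.355, 1.375),
                               nuc_ri = c(1.425, 1.445), shape = c(48, 48),
                               pixel_pitch = 16 / 60, n_slices = 1,
                               z_spacing = 100, optics = optical_stack(),
                               noise = "none", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (boundary_index < 2 || boundary_index > n_t - 1)
    stop("'boundary_index' must leave at least two points per phase")
  # scripted multiplier curve, piecewise linear in time
  m1 <- 1 + rates[1]; m2 <- m1 * (1 + rates[2])
  mult <- c(seq(1, m1, length.out = boundary_index),
            seq(m1, m2, length.out = n_t - boundary_index + 1L)[-1L])
  centre_px <- (shape + 1) / 2
  cell <- ellipse_mask(shape, centre_px, axes, pixel_pitch)
  nucleus <- if (nucleus_fraction > 0)
    ellipse_mask(shape, centre_px, axes * nucleus_fraction, pixel_pitch)
  else cell & FALSE
  ri0 <- cell_ri_field(cell, nucleus, cyt_ri, nuc_ri, optics$n1)
  wl <- wavelength_set()
  h_nm <- height * 1000
  z_positions <- seq(0, by = z_spacing, length.out = n_slices)
  focus_z <- z_positions[ceiling(n_slices / 2)]
  Tt <- fresnel_prefactor(optics)
  vox <- pixel_pitch^2 * height
  phantoms <- vector("list", n_t)
  truth_mass <- numeric(n_t)
  for (t in seq_len(n_t)) {
    ri <- ri0
    ri[cell] <- optics$nw + (ri0[cell] - optics$nw) * mult[t]
    dn_map <- (ri - optics$n1) / optics$n1
    img <- array(0, c(shape, length(wl), n_slices))
    for (j in seq_len(n_slices)) {
      dz_eff <- focus_z - z_positions[j]
      img[, , , j] <- phantom_slice(dn_map, 0, h_nm, dz_eff, optics, wl,
                                    envelope = n_slices > 1L)
    }
    img <- apply_noise(img, noise, noise_sd)
    phantoms[[t]] <- list(
      stack = interferogram_stack(img, wl = wl, z_positions = z_positions,
                                  background = rep(Tt^2, length(wl)),
                                  pixel_pitch = pixel_pitch),
      optics = optics,
      truth = list(kind = "cell", ri_map = ri, cell_mask = cell,
                   nucleus_mask = nucleus, height = height))
    truth_mass[t] <- sum((ri[cell] - optics$nw) / optics$alpha) * vox
  }
  list(phantoms = phantoms,
       truth = list(kind = "growth_series",
                    timepoints = (seq_len(n_t) - 1L) * timestep,
                    mass = truth_mass, boundary_index = boundary_index,
                    rates = rates, seed = seed))
}
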