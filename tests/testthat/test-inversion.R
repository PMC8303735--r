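opt <- optical_stack()
wl <- wavelength_set()
lam <- as.numeric(wl)

test_that("grid_spec validates axes and fit_error behaves like an SSE", {
  expect_error(grid_spec(dn_min = 0.1, dn_max = 0), "dn")
  expect_error(grid_spec(dz_step = 0), "dz")
  expect_equal(fit_error(c(1, 1.1), c(1, 1)), 0.01)
  expect_identical(fit_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fit_error(c(1, 2), c(2, 1)), fit_error(c(2, 1), c(1, 2)))
  expect_error(fit_error(1:3, 1:2), "same length")
})

test_that("ergodic search equals the literal brute-force oracle on small grids", {
  g <- grid_spec(dn_min = -0.02, dn_max = 0.02, dn_step = 1e-3,
                 dz_min = -5, dz_max = 5, dz_step = 0.5)
  set.seed(3)
  for (i in 1:12) {
    dn0 <- runif(1, -0.02, 0.02)
    dz0 <- runif(1, -5, 5)
    m <- slab_normalized_intensity(0, 3000, dn0, dz0, opt$n1, lam)
    if (i %% 3 == 0) m <- m + rnorm(4, 0, 0.01)  # noisy measurements too
    a <- ergodic_search(m, opt, g, c(0, 3000), wl)
    b <- oracle_search_dn_dz(m, lam, opt$n1, 0, 3000, g)
    expect_identical(a$delta_n, b$delta_n)
    expect_identical(a$residual, b$residual)
    if (!a$degenerate) expect_identical(a$delta_z, b$delta_z)
  }
})

test_that("grids whose origin is a step multiple contain zero exactly", {
  # a pure-background measurement must land on dn = 0 exactly, which
  # requires the grid value itself to be exactly zero
  g <- grid_spec(dn_min = -0.003, dn_max = 0.003, dn_step = 1e-4,
                 dz_min = -3, dz_max = 3, dz_step = 0.1)
  r <- ergodic_search(rep(1, 4), opt, g, c(0, 3000), wl)
  expect_identical(r$delta_n, 0)
  expect_identical(r$delta_z, 0)
  expect_identical(r$residual, 0)
  expect_true(r$degenerate)
  b <- oracle_search_dn_dz(rep(1, 4), lam, opt$n1, 0, 3000, g)
  expect_identical(b$delta_n, 0)
  expect_identical(b$delta_z, 0)
})

test_that("an exact-tie measurement resolves by the documented tie-break chain", {
  # single wavelength, slab spanning one full period: the model
  # coefficient is ~0 for every dz, so all contrasts fit equally and the
  # chain |dz| -> |dn| -> lexicographic must land on (0, 0)
  wl1 <- wavelength_set(447)
  b1 <- 447 / (2 * opt$n1)
  g <- grid_spec(dn_min = -0.02, dn_max = 0.02, dn_step = 1e-3,
                 dz_min = -5, dz_max = 5, dz_step = 0.5)
  a <- ergodic_search(1.05, opt, g, c(0, b1), wl1)
  o <- oracle_search_dn_dz(1.05, 447, opt$n1, 0, b1, g)
  expect_identical(a$delta_n, o$delta_n)
  expect_identical(a$delta_n, 0)
  expect_true(a$degenerate)
  expect_equal(a$residual, 0.05^2)
})

test_that("on-grid truth is recovered exactly on the default grid", {
  m <- slab_normalized_intensity(0, 3000, 0.05, 50, opt$n1, lam)
  r <- ergodic_search(m, opt, grid_spec(), c(0, 3000), wl)
  expect_identical(r$delta_n, 0.05)
  expect_identical(r$delta_z, 50)
  expect_lt(r$residual, 1e-30)
  expect_false(r$degenerate)
})

test_that("off-grid truth is recovered within a few grid steps at workable contrast", {
  # the joint quantization of (dn, dz) couples the two axes: rounding dz
  # shifts the best-fitting contrast by a small multiple of the contrast
  # step, and at very low contrast the dz axis itself becomes poorly
  # conditioned.  The bounds below reflect what the search actually
  # guarantees for contrasts of cellular magnitude (|dn| >= 0.01): a few
  # steps on each axis, not one.
  g <- grid_spec()
  set.seed(21)
  for (i in 1:5) {
    dn0 <- sign(runif(1, -1, 1)) * runif(1, 0.01, 0.2)
    dz0 <- runif(1, -250, 250)
    m <- slab_normalized_intensity(0, 3000, dn0, dz0, opt$n1, lam)
    r <- ergodic_search(m, opt, g, c(0, 3000), wl)
    expect_lte(abs(r$delta_n - dn0), 10 * g$dn_step)
    expect_lte(abs(r$delta_z - dz0), 3 * g$dz_step)
    # the grid minimum fits at least as well as the rounded truth does
    m_round <- slab_normalized_intensity(0, 3000,
                                         round(dn0 / g$dn_step) * g$dn_step,
                                         round(dz0 / g$dz_step) * g$dz_step,
                                         opt$n1, lam)
    # small slack for last-ulp differences in the model evaluation
    expect_lte(r$residual, fit_error(m, m_round) * (1 + 1e-9) + 1e-30)
  }
  # a representative well-conditioned instance lands within one step
  m1 <- slab_normalized_intensity(0, 3000, 0.054321, 49.876, opt$n1, lam)
  r1 <- ergodic_search(m1, opt, g, c(0, 3000), wl)
  expect_lte(abs(r1$delta_n - 0.054321), g$dn_step)
  expect_lte(abs(r1$delta_z - 49.876), g$dz_step)
})

test_that("perturbed measurements yield a nonzero residual bounded by the noise energy", {
  # the grid point at the (on-grid) truth achieves exactly the injected
  # noise energy, so the global minimum can never exceed it
  g <- grid_spec()
  m <- slab_normalized_intensity(0, 3000, 0.05, 50, opt$n1, lam)
  e <- c(1, -1, 1, -1) * 0.002
  r <- ergodic_search(m + e, opt, g, c(0, 3000), wl)
  expect_gt(r$residual, 0)
  expect_lte(r$residual, fit_error(m + e, m) * (1 + 1e-9))
})

test_that("one wavelength is ambiguous in delta_z where four are unique", {
  dn0 <- 0.0512345; dz0 <- 100.05   # both off-grid
  period <- 447 / (2 * opt$n1)      # dz period of the 447 nm channel
  win <- function(centre) grid_spec(dz_min = centre - 1, dz_max = centre + 1,
                                    dz_step = 0.1)
  # single wavelength: the slab model repeats every period, so a window
  # around the alias dz0 - period fits exactly as well as the truth window
  wl1 <- wavelength_set(447)
  m1 <- slab_normalized_intensity(0, 3000, dn0, dz0, opt$n1, 447)
  r_true <- ergodic_search(m1, opt, win(dz0), c(0, 3000), wl1)
  r_alias <- ergodic_search(m1, opt, win(dz0 - period), c(0, 3000), wl1)
  expect_lt(r_true$residual, 1e-8)
  expect_lt(r_alias$residual, 1e-8)
  # four wavelengths: the alias window misfits by orders of magnitude
  m4 <- slab_normalized_intensity(0, 3000, dn0, dz0, opt$n1, lam)
  r4_true <- ergodic_search(m4, opt, win(dz0), c(0, 3000), wl)
  r4_alias <- ergodic_search(m4, opt, win(dz0 - period), c(0, 3000), wl)
  expect_lt(r4_true$residual, 1e-7)
  expect_gt(r4_alias$residual, 1e-4)
  expect_lte(abs(r4_true$delta_z - dz0), 0.1)
})

test_that("invert_image recovers per-pixel maps and flags background as degenerate", {
  shape <- c(6, 5)
  dn_map <- matrix(0, shape[1], shape[2])
  dn_map[2:4, 2:3] <- 0.04
  Tt <- fresnel_prefactor(opt)
  img <- array(0, c(shape, 4, 1))
  for (l in 1:4)
    img[, , l, 1] <- Tt^2 * slab_normalized_intensity(0, 2000, dn_map, 30,
                                                      opt$n1, lam[l])
  st <- interferogram_stack(img, wl, z_positions = 0,
                            background = rep(Tt^2, 4))
  f <- invert_image(st, opt, grid_spec(), c(0, 2000))
  expect_s3_class(f, "recovered_field")
  expect_identical(f$delta_n_map[3, 2], 0.04)
  expect_identical(f$delta_z_map[3, 2], 30)
  expect_identical(f$delta_n_map[1, 1], 0)
  expect_true(all(f$degenerate_map[dn_map == 0]))
  expect_false(any(f$degenerate_map[dn_map != 0]))
  expect_equal(f$ri_map, opt$n1 * (1 + f$delta_n_map))
  # degenerate pixels report dz = 0
  expect_true(all(f$delta_z_map[dn_map == 0] == 0))
})

test_that("wafer search equals its brute-force oracle and handles degeneracy", {
  wopt <- wafer_optics()
  dnl <- (wopt$n1 - wopt$n0) / wopt$n1
  g <- grid_spec(t_min = 0, t_max = 40, t_step = 2,
                 dz_min = -4, dz_max = 4, dz_step = 1)
  set.seed(5)
  for (i in 1:8) {
    ph <- make_wafer(runif(1, 0, 40), runif(1, -4, 4), shape = c(2, 2))
    m <- normalized_slice(ph$stack, 1)[1, 1, ]
    a <- invert_wafer(m, wopt, g)
    b <- oracle_search_wafer(m, lam, wopt$n1, dnl, g)
    expect_identical(a$thickness, b$thickness)
    expect_identical(a$residual, b$residual)
    if (!a$degenerate) expect_identical(a$delta_z, b$delta_z)
  }
  # flat measurement: zero thickness, degenerate, dz reported 0
  r0 <- invert_wafer(rep(1, 4), wopt, g)
  expect_identical(r0$thickness, 0)
  expect_identical(r0$delta_z, 0)
  expect_true(r0$degenerate)
})

test_that("the wafer model symmetry C(t, dz) = C(t + 2 dz, -dz) is an exact tie", {
  # the pair (t, dz) and (t + 2 dz, -dz) produce identical coefficients,
  # so their residuals agree to full precision and only the tie-break
  # order decides between them
  k <- 4 * pi * 1.45 / lam
  # when t + 2 dz evaluates exactly (integer arguments), the tie is bitwise:
  # cos is even, and the second argument t + 2 dz + (-dz) == t + dz exactly
  for (par in list(c(38, -3), c(8, -2))) {
    t <- par[1]; dz <- par[2]
    C1 <- cos(k * dz) - cos(k * (t + dz))
    C2 <- cos(k * -dz) - cos(k * ((t + 2 * dz) + -dz))
    expect_identical(C1, C2)
  }
  # for general real arguments the tie is exact in real arithmetic; in
  # floating point the two association orders agree to rounding accuracy
  for (par in list(c(120.4, 17.3), c(36.675, -1.72))) {
    t <- par[1]; dz <- par[2]
    C1 <- cos(k * dz) - cos(k * (t + dz))
    C2 <- cos(k * -dz) - cos(k * ((t + 2 * dz) + -dz))
    expect_equal(C1, C2, tolerance = 1e-12)
  }
  # and the addition-identity evaluation used by the scan matches the
  # literal cosine difference to rounding accuracy
  for (t in c(285, 500, 1234.5)) for (dz in c(-7.3, 0, 2.1)) {
    lit <- cos(k * dz) - cos(k * (t + dz))
    idn <- cos(k * dz) - (cos(k * t) * cos(k * dz) - sin(k * t) * sin(k * dz))
    expect_equal(idn, lit, tolerance = 1e-12)
    expect_lt(max(abs(idn - lit)), 1e-12)
  }
})

test_that("select_focus picks the minimal-median-residual slice, ties to the lowest", {
  mk <- function(res) list(delta_n_map = matrix(0.01, 3, 3),
                           residual_map = matrix(res, 3, 3),
                           noise_floor = 3e-4)
  expect_identical(select_focus(list(mk(0.2), mk(0.05), mk(0.4))), 2L)
  expect_identical(select_focus(list(mk(0.1), mk(0.1))), 1L)
  expect_error(select_focus(list()), "empty")
})

test_that("focus_field unwraps stacks and rejects other objects", {
  ph <- make_cell(shape = c(16, 16), axes = c(1.5, 1.2),
                  nucleus_fraction = 0, z_total = 400, z_spacing = 200,
                  seed = 1)
  rec <- invert_image(ph$stack, ph$optics, grid_spec(), c(0, 3000))
  expect_s3_class(rec, "recovered_stack")
  f <- focus_field(rec)
  expect_s3_class(f, "recovered_field")
  expect_identical(f, rec$slices[[rec$focus_index]])
  expect_identical(focus_field(f), f)
  expect_error(focus_field(1:3), "not a recovered field")
})
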