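test_that("phantom generators are bit-reproducible given a seed", {
  a <- make_cell(shape = c(24, 24), z_total = 200, z_spacing = 100, seed = 5)
  b <- make_cell(shape = c(24, 24), z_total = 200, z_spacing = 100, seed = 5)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$truth$ri_map, b$truth$ri_map)
  s1 <- make_microsphere_field(seed = 9)
  s2 <- make_microsphere_field(seed = 9)
  expect_identical(s1$stack$images, s2$stack$images)
  expect_identical(s1$truth$ri_true, s2$truth$ri_true)
  c1 <- make_cell(shape = c(24, 24), z_total = 200, z_spacing = 100, seed = 6)
  expect_false(identical(a$stack$images, c1$stack$images))
})

test_that("a zero-thickness wafer is optically flat", {
  ph <- make_wafer(0, shape = c(4, 4))
  expect_equal(normalized_slice(ph$stack, 1),
               array(1, c(4, 4, 4)))
})

test_that("wafer intensities follow the closed-form slab model", {
  ph <- make_wafer(500, delta_z = 12, shape = c(3, 3))
  ihat <- normalized_slice(ph$stack, 1)
  lam <- as.numeric(wavelength_set())
  for (l in 1:4)
    expect_equal(ihat[, , l],
                 matrix(slab_normalized_intensity(0, 500, ph$truth$dn_layer,
                                                  12, 1.45, lam[l]), 3, 3))
})

test_that("microsphere centre pixels follow the slab model over the chord", {
  ph <- make_microsphere_field(material_ri = 1.59, n_spheres = 5, seed = 4)
  ihat <- normalized_slice(ph$stack, 1)
  lam <- as.numeric(wavelength_set())
  ctr <- ph$truth$centres
  for (s in seq_len(nrow(ctr))) for (l in 1:4)
    expect_equal(ihat[ctr[s, 1], ctr[s, 2], l],
                 slab_normalized_intensity(0, 500, ph$truth$dn_true[s], 0,
                                           1.59, lam[l]))
  # background pixels are exactly at the reference level
  bg <- ihat[, , 1]; bg[ctr] <- NA
  expect_true(all(bg == 1, na.rm = TRUE))
  # zero jitter means invisible spheres
  ph0 <- make_microsphere_field(ri_jitter = 0, n_spheres = 5, seed = 4)
  expect_true(all(normalized_slice(ph0$stack, 1) == 1))
})

test_that("microsphere placement is non-overlapping and inside the margin", {
  ph <- make_microsphere_field(n_spheres = 20, seed = 7)
  ctr <- ph$truth$centres
  expect_identical(nrow(ctr), 20L)
  d <- as.matrix(stats::dist(ctr, method = "maximum"))
  diag(d) <- Inf
  expect_gte(min(d), 3)   # separation >= sphere footprint + 1
  expect_true(all(ph$truth$ri_true >= 1.588 & ph$truth$ri_true <= 1.592))
})

test_that("cell phantom mass bookkeeping is consistent along two routes", {
  ph <- make_cell(seed = 42, z_total = 200, z_spacing = 100)
  tr <- ph$truth
  # voxel-sum route is internally additive
  expect_equal(tr$masses$total, tr$masses$nuclear + tr$masses$cytoplasmic)
  # voxel sum vs continuous-geometry integral agree to pixelation accuracy
  expect_lt(abs(tr$masses$total / tr$masses_continuous$total - 1), 0.05)
  expect_lt(abs(tr$masses$nuclear / tr$masses_continuous$nuclear - 1), 0.08)
  # the gap shrinks when the footprint is sampled twice as finely
  fine <- make_cell(seed = 42, z_total = 200, z_spacing = 100,
                    shape = c(128, 128), pixel_pitch = 16 / 120)
  expect_lt(abs(fine$truth$masses$total / fine$truth$masses_continuous$total - 1),
            abs(tr$masses$total / tr$masses_continuous$total - 1))
})

test_that("cell phantom geometry follows its parameters", {
  ph <- make_cell(seed = 3, nucleus_fraction = 0, z_total = 200,
                  z_spacing = 100)
  expect_false(any(ph$truth$nucleus_mask))
  expect_identical(ph$truth$masses$nuclear, 0)
  # nucleus RI range sits above the segmentation threshold
  ph2 <- make_cell(seed = 3, z_total = 200, z_spacing = 100)
  nuc_ri <- ph2$truth$ri_map[ph2$truth$nucleus_mask]
  cyt_ri <- ph2$truth$ri_map[ph2$truth$cell_mask & !ph2$truth$nucleus_mask]
  expect_true(all(nuc_ri > 1.42))
  expect_true(all(cyt_ri < 1.42))
  expect_identical(ph2$truth$focus_index,
                   which.min(abs(ph2$stack$z_positions - 100)))
})

test_that("osmotic series conserves true mass exactly while the footprint shrinks", {
  ser <- make_osmotic_series(seed = 11, n_slices = 1)
  tm <- ser$truth$total_mass
  expect_equal(tm, rep(tm[1], length(tm)), tolerance = 1e-12)
  expect_equal(ser$truth$nuclear_mass,
               rep(ser$truth$nuclear_mass[1], 11), tolerance = 1e-12)
  shrink <- 1 - min(ser$truth$size_px) / max(ser$truth$size_px)
  expect_gte(shrink, 0.12)
  expect_identical(length(ser$phantoms), 11L)
})

test_that("growth series follows the scripted two-phase trajectory exactly", {
  ser <- make_growth_series(seed = 2)
  tr <- ser$truth
  k <- tr$boundary_index
  m <- tr$mass
  expect_equal((m[k] - m[1]) / m[1], tr$rates[1], tolerance = 1e-9)
  expect_equal((m[length(m)] - m[k]) / m[k], tr$rates[2], tolerance = 1e-9)
  # piecewise linear in time within each phase
  expect_equal(diff(m[1:k]), rep(diff(m[1:2]), k - 1), tolerance = 1e-9)
  expect_identical(tr$timepoints, (0:11) * 2)
  expect_error(make_growth_series(boundary_index = 1), "two points")
})

test_that("noise models behave as declared", {
  ph0 <- make_wafer(300, shape = c(16, 16), seed = 1)
  phn <- make_wafer(300, shape = c(16, 16), seed = 1,
                    noise = "gaussian_additive", noise_sd = 0.01)
  expect_false(identical(ph0$stack$images, phn$stack$images))
  expect_true(all(phn$stack$images >= 0))
  expect_lt(abs(mean(phn$stack$images) - mean(ph0$stack$images)), 0.005)
  # sd = 0 is a no-op
  ph2 <- make_wafer(300, shape = c(16, 16), seed = 1,
                    noise = "gaussian_additive", noise_sd = 0)
  expect_identical(ph0$stack$images, ph2$stack$images)
})
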