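test_that("nucleus threshold is strict", {
  ri <- matrix(c(1.41, 1.42, 1.4200001, 1.45), 2, 2)
  m <- threshold_nucleus(ri)
  expect_identical(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(threshold_nucleus(matrix(NA_real_, 1, 1)), "finite")
})

test_that("clean_mask removes speckles and matches a plain erosion oracle", {
  mask <- matrix(FALSE, 25, 25)
  mask[6:20, 6:20] <- TRUE      # solid block survives
  mask[2, 2] <- TRUE            # isolated speckle is erased
  out <- clean_mask(mask, erosion_radius = 2, min_size = 20)
  expect_false(out[2, 2])
  # oracle: erosion keeps a pixel iff the disk around it fits in the mask
  br <- EBImage::makeBrush(5, shape = "disc")
  off <- which(br > 0, arr.ind = TRUE) - 3L
  expected <- matrix(FALSE, 25, 25)
  for (r in 3:23) for (cc in 3:23)
    expected[r, cc] <- all(mask[cbind(r + off[, 1], cc + off[, 2])])
  expect_identical(out, expected)
  # an all-false mask stays empty without errors
  expect_identical(clean_mask(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
  # min_size removes small surviving components
  small <- matrix(FALSE, 20, 20)
  small[5:9, 5:9] <- TRUE       # 25 px -> 1 px after erosion by r = 2
  expect_false(any(clean_mask(small, erosion_radius = 2, min_size = 20)))
  expect_true(any(clean_mask(small, erosion_radius = 2, min_size = 1)))
})

test_that("canny_edges traces a closed ring around a sharp disk", {
  ri <- matrix(1.36, 41, 41)
  r <- matrix(seq_len(41), 41, 41); cc <- t(r)
  disk <- (r - 21)^2 + (cc - 21)^2 <= 100
  ri[disk] <- 1.44
  edges <- canny_edges(ri)
  expect_true(any(edges))
  # all edge pixels lie near the true boundary (radius 10 +/- 3 px)
  rad <- sqrt((r - 21)^2 + (cc - 21)^2)
  expect_true(all(rad[edges] > 7 & rad[edges] < 13))
  # the ring encloses interior pixels
  filled <- EBImage::fillHull(edges * 1) > 0
  expect_gt(sum(filled), sum(edges))
  expect_true(filled[21, 21])
  # a flat image has no edges
  expect_false(any(canny_edges(matrix(1.4, 20, 20))))
})

test_that("refine_nucleus recovers sub-threshold interior holes", {
  ri <- matrix(1.36, 41, 41)
  r <- matrix(seq_len(41), 41, 41); cc <- t(r)
  truth <- (r - 21)^2 + (cc - 21)^2 <= 100
  ri[truth] <- 1.435
  holes <- truth & ((r - 19)^2 + (cc - 22)^2 <= 4)
  ri[holes] <- 1.41                       # textured dropout under threshold
  cleaned <- clean_mask(threshold_nucleus(ri))
  expect_false(any(cleaned & holes))      # holes lost by thresholding
  refined <- refine_nucleus(cleaned, ri)
  expect_gte(dice_overlap(refined, truth), 0.95)
  expect_true(all(refined[holes]))        # holes recovered
})

test_that("refine_nucleus falls back with a warning when no contour is found", {
  mask <- matrix(FALSE, 15, 15); mask[6:9, 6:9] <- TRUE
  flat <- matrix(1.43, 15, 15)            # no gradient anywhere
  expect_warning(out <- refine_nucleus(mask, flat), "no edges")
  expect_identical(out, mask)
  # empty input passes through untouched
  empty <- matrix(FALSE, 15, 15)
  expect_identical(refine_nucleus(empty, flat), empty)
})

test_that("decompose_masks enforces the partition invariants", {
  nuc <- matrix(FALSE, 6, 6); nuc[3:4, 3:4] <- TRUE
  cell <- matrix(FALSE, 6, 6); cell[2:5, 2:5] <- TRUE
  s <- decompose_masks(nuc, cell)
  expect_s3_class(s, "segmentation_mask")
  expect_false(any(s$nucleus_mask & s$cytoplasm_mask))
  expect_identical(s$nucleus_mask | s$cytoplasm_mask, s$cell_mask)
  expect_true(all(s$cell_mask[s$nucleus_mask]))
  # nucleus leaking outside the cell is clipped with a warning
  nuc2 <- nuc; nuc2[1, 1] <- TRUE
  expect_warning(s2 <- decompose_masks(nuc2, cell), "clipping")
  expect_false(s2$nucleus_mask[1, 1])
  expect_error(decompose_masks(nuc, matrix(TRUE, 3, 3)), "differ")
})

test_that("segment_nucleus matches the phantom ground truth", {
  ph <- make_cell(shape = c(48, 48), z_total = 400, z_spacing = 200,
                  seed = 42)
  rec <- invert_image(ph$stack, ph$optics, grid_spec(),
                      c(0, ph$truth$height * 1000))
  field <- focus_field(rec)
  seg <- segment_nucleus(field)
  expect_gte(dice_overlap(seg$nucleus_mask, ph$truth$nucleus_mask), 0.95)
  expect_gte(dice_overlap(seg$cell_mask, ph$truth$cell_mask), 0.95)
  # cell support without erosion keeps the full footprint
  expect_lte(abs(sum(seg$cell_mask) - sum(ph$truth$cell_mask)),
             0.05 * sum(ph$truth$cell_mask))
})

test_that("cell_support fills interior dropouts and drops speckles", {
  f <- structure(list(delta_n_map = matrix(0, 30, 30), noise_floor = 3e-4),
                 class = "recovered_field")
  f$delta_n_map[8:22, 8:22] <- 0.02
  f$delta_n_map[15, 15] <- 0        # interior dropout at the carrier index
  f$delta_n_map[2, 2] <- 0.02       # isolated speckle
  m <- cell_support(f)
  expect_true(m[15, 15])            # hole filled
  expect_false(m[2, 2])             # speckle removed
  expect_identical(sum(m), 15L * 15L)
})
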