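test_that("CLAHE is deterministic, bounded, and a no-op on flat slices", {
  const <- intensity_volume(array(0.4, c(6, 32, 32)))
  out <- clahe_enhance(const)
  expect_equal(out$voxels, const$voxels)
  expect_identical(out$shape, const$shape)

  ph <- make_test_phantom(21L, contrast_gap = 0.1, noise_sd = 0.02)
  e1 <- clahe_enhance(ph$volume)
  e2 <- clahe_enhance(ph$volume)
  expect_identical(e1$voxels, e2$voxels)
  expect_gte(min(e1$voxels), 0)
  expect_lte(max(e1$voxels), 1)
  expect_identical(e1$shape, ph$volume$shape)
})

test_that("CLAHE increases contrast on low-contrast canal slices", {
  ph <- make_test_phantom(22L, contrast_gap = 0.1, noise_sd = 0.02)
  enhanced <- clahe_enhance(ph$volume)
  canal_slices <- which(apply(ph$label$voxels, 1, sum) > 0)
  sd_before <- vapply(canal_slices, function(s) sd(ph$volume$voxels[s, , ]),
                      numeric(1))
  sd_after <- vapply(canal_slices, function(s) sd(enhanced$voxels[s, , ]),
                     numeric(1))
  expect_true(all(sd_after > sd_before))
})

test_that("tile grids larger than the slice are clamped with a warning", {
  old <- canalseg::set_log_level("info")
  on.exit(canalseg::set_log_level("info"), add = TRUE)
  small <- intensity_volume(array(runif(4 * 10 * 10), c(4, 10, 10)))
  expect_message(clahe_enhance(small, clahe_params(tile_grid = c(16L, 16L))),
                 "clamped")
})

test_that("canal openings are located at the component extremes", {
  tube <- binary_mask(straight_tube(c(60L, 12L, 12L), 11, 51, c(6, 6), 1.5))
  ends <- locate_foramina(tube)
  ends <- ends[order(ends[, 1]), ]
  expect_lte(max(abs(ends[1, ] - c(10, 5, 5))), 1)
  expect_lte(max(abs(ends[2, ] - c(50, 5, 5))), 1)

  # a small distant second component is ignored
  two <- tube$voxels
  two[58:59, 10:11, 10:11] <- 1
  ends2 <- locate_foramina(binary_mask(two))
  expect_true(all(ends2[, 1] <= 52))

  # phantom: located ends sit near the specified foramina
  spec <- phantom_spec(shape = c(48L, 48L, 48L), n_control_points = 3L,
                       radius_range = c(2, 3), seed = 12L)
  ph <- generate_phantom(spec)
  ends3 <- locate_foramina(ph$label)
  d_match <- function(p, q) sqrt(sum((p - q)^2))
  best <- min(d_match(ends3[1, ], spec$endpoints[1, ]) +
                d_match(ends3[2, ], spec$endpoints[2, ]),
              d_match(ends3[1, ], spec$endpoints[2, ]) +
                d_match(ends3[2, ], spec$endpoints[1, ]))
  expect_lte(best / 2, spec$radius_range[2] + 1)

  expect_error(locate_foramina(binary_mask(array(0, c(4, 4, 4)))), "empty")
})

test_that("cropping takes the tight expanded component box", {
  vox <- array(0, c(64, 20, 20))
  vox[11:51, 6:9, 6:9] <- 1
  lab <- binary_mask(vox)
  vol <- intensity_volume(array(runif(64 * 20 * 20), c(64, 20, 20)))
  cr <- crop_to_canal(vol, lab, margin_mm = 0)
  expect_equal(cr$box$lo, c(10L, 5L, 5L))
  expect_equal(cr$box$hi, c(51L, 9L, 9L))
  expect_equal(dim(cr$volume$voxels), c(41L, 4L, 4L))
  # cropped label keeps every component voxel
  expect_equal(sum(cr$label$voxels), sum(vox))
})

test_that("cropping conserves foreground and restore inverts it", {
  ph <- make_test_phantom(31L, shape = c(48L, 48L, 48L))
  vol <- ph$volume
  lab <- ph$label
  for (margin in c(0, 3)) {
    cr <- crop_to_canal(vol, lab, margin)
    expect_equal(sum(cr$label$voxels), sum(lab$voxels))
    back <- restore_to_original(cr$label, cr$box)
    expect_identical(back$voxels, lab$voxels)
    # cropped volume content matches the parent inside the box
    rs <- lapply(1:3, function(j) (cr$box$lo[j] + 1):cr$box$hi[j])
    expect_identical(cr$volume$voxels, vol$voxels[rs[[1]], rs[[2]], rs[[3]]])
  }
})

test_that("a half-grid canal crops away at least half of the voxels", {
  # canal confined to one octant-ish region of a 64^3 grid
  spec <- phantom_spec(shape = c(64L, 64L, 64L),
                       endpoints = rbind(c(8, 8, 8), c(28, 26, 24)),
                       n_control_points = 3L, radius_range = c(2, 3),
                       seed = 41L)
  ph <- generate_phantom(spec)
  cr <- crop_to_canal(ph$volume, ph$label, margin_mm = 3)
  frac <- prod(dim(cr$volume$voxels)) / prod(ph$volume$shape)
  expect_lte(frac, 0.5)
})

test_that("restore places content flush at the box origin", {
  box <- crop_box(c(0L, 0L, 0L), c(3L, 3L, 3L), c(8L, 8L, 8L))
  patch <- soft_mask(array(runif(27), c(3, 3, 3)))
  full <- restore_to_original(patch, box)
  expect_identical(full$voxels[1:3, 1:3, 1:3], patch$voxels)
  expect_true(all(full$voxels[4:8, , ] == 0))

  # all-zero patch restores to an all-zero parent
  zero <- restore_to_original(
    binary_mask(array(0, c(3, 3, 3))), box)
  expect_true(all(zero$voxels == 0))

  expect_error(restore_to_original(soft_mask(array(0, c(2, 2, 2))), box),
               "does not match")
})
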