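test_that("a two-control-point centerline is the straight segment", {
  spec <- phantom_spec(shape = c(40L, 40L, 40L), n_control_points = 2L,
                       seed = 7L)
  cl <- make_centerline(spec)
  a <- spec$endpoints[1, ]
  b <- spec$endpoints[2, ]
  # arc length equals the Euclidean endpoint distance
  seg <- diff(cl)
  arc <- sum(sqrt(rowSums(seg^2)))
  expect_equal(arc, sqrt(sum((a - b)^2)), tolerance = 0.5)
  # every sample lies on the segment (distance to the line is ~0)
  dir <- (b - a) / sqrt(sum((b - a)^2))
  rel <- sweep(cl, 2, a)
  proj <- rel %*% dir %*% t(dir)
  expect_lt(max(abs(rel - proj)), 1e-8)
})

test_that("centerline generation is deterministic and stays inside the grid", {
  spec <- phantom_spec(seed = 11L)
  cl1 <- make_centerline(spec)
  cl2 <- make_centerline(spec)
  expect_identical(cl1, cl2)
  expect_true(all(cl1 >= 0))
  expect_true(all(sweep(cl1, 2, spec$shape - 1) <= 0))
  # arc steps bounded by 0.5 voxels
  expect_lte(max(sqrt(rowSums(diff(cl1)^2))), 0.5 + 1e-9)
})

test_that("close endpoints are rejected", {
  expect_error(make_centerline(
    phantom_spec(shape = c(32L, 32L, 32L),
                 endpoints = rbind(c(10, 10, 10), c(12, 10, 10)),
                 radius_range = c(2, 4))),
    "4 \\* r_max")
})

test_that("tube rasterization matches a brute-force distance oracle", {
  # straight axis-aligned centerline at 0.25-voxel steps, radius 1
  cl <- cbind(seq(5, 15, by = 0.25), 6, 6)
  mask <- rasterize_tube(cl, 1, c(20L, 12L, 12L))
  oracle <- array(0, c(20, 12, 12))
  for (d in 1:20) for (h in 1:12) for (w in 1:12) {
    dmin <- min(sqrt((d - 1 - cl[, 1])^2 + (h - 1 - cl[, 2])^2 +
                       (w - 1 - cl[, 3])^2))
    # distance to the segment equals distance to the dense sample set here
    if (dmin <= 1) oracle[d, h, w] <- 1
  }
  expect_identical(mask$voxels, oracle)

  # zero radii are clamped to 1 voxel
  thin <- rasterize_tube(cl, 0, c(20L, 12L, 12L))
  expect_identical(thin$voxels, oracle)

  expect_error(rasterize_tube(cbind(2, 6, 6), 5, c(20L, 12L, 12L)),
               "exits the grid")
})

test_that("26-connected labelling agrees with a flood-fill oracle", {
  flood_oracle <- function(m) {
    sh <- dim(m)
    lab <- array(0L, sh)
    nxt <- 0L
    for (s in which(m == 1 & lab == 0)) {
      if (lab[s] > 0) next
      nxt <- nxt + 1L
      queue <- s
      lab[s] <- nxt
      while (length(queue)) {
        i <- queue[1]; queue <- queue[-1]
        co <- arrayInd(i, sh)
        for (dd in -1:1) for (dh in -1:1) for (dw in -1:1) {
          n <- co + c(dd, dh, dw)
          if (any(n < 1) || any(n > sh)) next
          j <- n[1] + sh[1] * (n[2] - 1 + sh[2] * (n[3] - 1))
          if (m[j] == 1 && lab[j] == 0) { lab[j] <- nxt; queue <- c(queue, j) }
        }
      }
    }
    lab
  }
  for (seed in 1:10) {
    set.seed(seed)
    m <- array(as.numeric(runif(125) < 0.3), c(5, 5, 5))
    got <- canalseg:::cs_label26(m, dim(m))
    want <- flood_oracle(m)
    expect_equal(max(got), max(want))
    # same partition (labels may be permuted)
    if (max(want) > 0)
      for (k in seq_len(max(want)))
        expect_equal(length(unique(got[want == k])), 1L)
  }
})

test_that("generated phantoms honour the intensity model and determinism", {
  spec0 <- phantom_spec(shape = c(32L, 32L, 32L), contrast_gap = 0.3,
                        noise_sd = 0, n_control_points = 3L, seed = 5L)
  # noiseless: canal exactly at 0.6 - gap, background near 0.6
  ph <- generate_phantom(spec0)
  expect_equal(mean(ph$volume$voxels[ph$label$voxels == 1]), 0.3)
  expect_equal(mean(ph$volume$voxels[ph$label$voxels == 0]), 0.6,
               tolerance = 0.02)

  spec1 <- phantom_spec(shape = c(32L, 32L, 32L), seed = 1L,
                        n_control_points = 3L)
  a <- generate_phantom(spec1)
  b <- generate_phantom(spec1)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$label$voxels, b$label$voxels)
  spec2 <- phantom_spec(shape = c(32L, 32L, 32L), seed = 2L,
                        n_control_points = 3L)
  expect_false(identical(a$volume$voxels,
                         generate_phantom(spec2)$volume$voxels))

  # single 26-connected component
  lab <- canalseg:::cs_label26(a$label$voxels, a$label$shape)
  expect_equal(max(lab), 1L)
})

test_that("the default phantom reproduces the class-imbalance regime", {
  ph <- generate_phantom(phantom_spec(seed = 3L))
  expect_lt(mean(ph$label$voxels), 0.02)
  lab <- canalseg:::cs_label26(ph$label$voxels, ph$label$shape)
  expect_equal(max(lab), 1L)
})

test_that("sparse annotations restrict the dense mask exactly", {
  ph <- make_test_phantom(9L)
  nonempty <- which(apply(ph$label$voxels, 1, sum) > 0)
  # all nonempty slices: stacking reproduces the mask
  sp_all <- make_sparse_annotation(ph$label, length(nonempty), seed = 1L)
  expect_identical(sparse_to_mask(sp_all)$voxels, ph$label$voxels)

  sp3 <- make_sparse_annotation(ph$label, 3L, seed = 1L)
  idx <- vapply(sp3$entries, function(e) e$slice, numeric(1))
  expect_length(idx, 3L)
  expect_true(all(diff(idx) > 0))

  # different seeds give different index sets with high probability
  draws <- vapply(1:100, function(s) {
    paste(vapply(make_sparse_annotation(ph$label, 3L, seed = s)$entries,
                 function(e) e$slice, numeric(1)), collapse = ",")
  }, character(1))
  expect_gt(length(unique(draws)), 10)

  empty <- binary_mask(array(0, c(8, 8, 8)))
  expect_error(make_sparse_annotation(empty, 1L), "empty")
})

test_that("circular expansion recovers straight tubes and interpolates", {
  # fully annotated straight constant-radius tube: near-exact recovery
  tube <- binary_mask(straight_tube(c(20L, 15L, 15L), 4, 17, c(8, 8), 3))
  n_slices <- sum(apply(tube$voxels, 1, sum) > 0)
  sp <- make_sparse_annotation(tube, n_slices, seed = 1L)
  circ <- make_circular_expansion(sp)
  cc <- confusion_counts(circ, tube)
  expect_gte(dice_score(cc), 0.95)

  # two identical annotated slices: a straight cylinder in between
  disk <- matrix(0, 15, 15)
  for (h in 1:15) for (w in 1:15)
    if ((h - 8)^2 + (w - 8)^2 <= 9) disk[h, w] <- 1
  sp2 <- sparse_annotation(list(list(slice = 2L, mask = disk),
                                list(slice = 10L, mask = disk)),
                           c(14L, 15L, 15L))
  circ2 <- make_circular_expansion(sp2)
  for (s in 3:11) expect_identical(circ2$voxels[s, , ], circ2$voxels[3, , ])
  expect_identical(circ2$voxels[4, , ], disk)

  # centroids drift linearly between annotated slices
  mk_disk <- function(ch, cw, r, H = 24, W = 24) {
    m <- matrix(0, H, W)
    for (h in 1:H) for (w in 1:W)
      if ((h - 1 - ch)^2 + (w - 1 - cw)^2 <= r^2) m[h, w] <- 1
    m
  }
  sp3 <- sparse_annotation(list(list(slice = 0L, mask = mk_disk(6, 6, 2)),
                                list(slice = 10L, mask = mk_disk(6, 16, 2))),
                           c(11L, 24L, 24L))
  circ3 <- make_circular_expansion(sp3)
  for (s in 0:10) {
    sl <- circ3$voxels[s + 1, , ]
    cen <- colMeans(which(sl == 1, arr.ind = TRUE)) - 1
    expect_equal(cen[[2]], 6 + s, tolerance = 0.35)
  }

  expect_error(make_circular_expansion(
    sparse_annotation(list(list(slice = 2L, mask = disk)), c(14L, 15L, 15L))),
    "at least 2")
})
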