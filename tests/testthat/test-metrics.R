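test_that("confusion counts agree with an explicit voxel loop", {
  set.seed(0)
  pr <- random_mask_pair(c(4, 4, 4))
  pred <- binary_mask(pr$a)
  ref <- binary_mask(pr$b)
  got <- confusion_counts(pred, ref)
  tp <- fp <- fn <- tn <- 0
  for (d in 1:4) for (h in 1:4) for (w in 1:4) {
    p <- pr$a[d, h, w]; r <- pr$b[d, h, w]
    if (p == 1 && r == 1) tp <- tp + 1
    if (p == 1 && r == 0) fp <- fp + 1
    if (p == 0 && r == 1) fn <- fn + 1
    if (p == 0 && r == 0) tn <- tn + 1
  }
  expect_equal(got, list(TP = tp, FP = fp, FN = fn, TN = tn))

  same <- confusion_counts(ref, ref)
  expect_equal(same$FP, 0)
  expect_equal(same$FN, 0)
  expect_equal(same$TP, sum(pr$b))

  comp <- binary_mask(1 - pr$b)
  cc <- confusion_counts(comp, ref)
  expect_equal(cc$TP, 0)
  expect_equal(cc$TN, 0)
})

test_that("dice and iou satisfy their exact algebraic identity", {
  expect_equal(dice_score(list(TP = 5, FP = 0, FN = 0)), 1)
  expect_equal(iou_score(list(TP = 5, FP = 0, FN = 0)), 1)
  expect_equal(dice_score(list(TP = 5, FP = 5, FN = 0)), 2 / 3)
  expect_equal(iou_score(list(TP = 5, FP = 5, FN = 0)), 1 / 2)
  set.seed(1)
  for (i in 1:1000) {
    c <- list(TP = sample(0:50, 1), FP = sample(0:50, 1),
              FN = sample(0:50, 1))
    if (c$TP + c$FP + c$FN == 0) next
    d <- dice_score(c); j <- iou_score(c)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
})

# independent surface + all-pairs distance oracle
hd_oracle <- function(a, b, spacing, percentile) {
  surf <- function(m) {
    sh <- dim(m)
    out <- NULL
    for (d in 1:sh[1]) for (h in 1:sh[2]) for (w in 1:sh[3]) {
      if (m[d, h, w] == 0) next
      nb <- c(if (d > 1) m[d - 1, h, w] else 0,
              if (d < sh[1]) m[d + 1, h, w] else 0,
              if (h > 1) m[d, h - 1, w] else 0,
              if (h < sh[2]) m[d, h + 1, w] else 0,
              if (w > 1) m[d, h, w - 1] else 0,
              if (w < sh[3]) m[d, h, w + 1] else 0)
      if (any(nb == 0)) out <- rbind(out, c(d, h, w) - 1)
    }
    out
  }
  A <- surf(a); B <- surf(b)
  dmat <- function(P, Q) {
    apply(P, 1, function(p) min(apply(Q, 1, function(q)
      sqrt(sum(((p - q) * spacing)^2)))))
  }
  p <- percentile / 100
  max(quantile(dmat(A, B), p, names = FALSE),
      quantile(dmat(B, A), p, names = FALSE))
}

test_that("surface Hausdorff distances match the all-pairs oracle", {
  tube <- binary_mask(straight_tube(c(12L, 9L, 9L), 3, 10, c(5, 5), 2))
  expect_equal(hausdorff(tube, tube, 100), 0)
  expect_equal(hausdorff(tube, tube, 95), 0)

  # two single voxels 4 voxels apart along D at 0.3 mm spacing
  a <- array(0, c(8, 4, 4)); a[2, 2, 2] <- 1
  b <- array(0, c(8, 4, 4)); b[6, 2, 2] <- 1
  expect_equal(hausdorff(binary_mask(a), binary_mask(b), 100), 1.2)

  set.seed(7)
  for (i in 1:20) {
    pr <- random_mask_pair(c(6, 6, 6), p = 0.3, nonempty = TRUE)
    pm <- binary_mask(pr$a); rm <- binary_mask(pr$b)
    for (pct in c(100, 95)) {
      want <- hd_oracle(pr$a, pr$b, c(0.3, 0.3, 0.3), pct)
      expect_equal(hausdorff(pm, rm, pct), want, tolerance = 1e-10)
    }
    # symmetry and HD95 <= HD
    expect_equal(hausdorff(pm, rm, 95), hausdorff(rm, pm, 95))
    expect_lte(hausdorff(pm, rm, 95), hausdorff(pm, rm, 100))
  }

  empty <- binary_mask(array(0, c(12, 9, 9)))
  expect_error(hausdorff(empty, tube), "undefined")
})

test_that("the hard centerline-Dice score reproduces the worked example", {
  lp <- line_pair()
  ref <- binary_mask(lp$ref)
  pred <- binary_mask(lp$pred)
  expect_equal(cldice_score(pred, ref), 2 / 3, tolerance = 1e-12)
  expect_equal(cldice_score(ref, ref), 1)

  # gap sensitivity: clDice penalizes a broken tube harder than Dice
  tube <- binary_mask(straight_tube(c(28L, 11L, 11L), 5, 24, c(6, 6), 2))
  gap <- tube$voxels
  gap[14:15, , ] <- 0
  gapped <- binary_mask(gap)
  cc <- confusion_counts(gapped, tube)
  expect_lt(cldice_score(gapped, tube), dice_score(cc))
})

test_that("self-similarity holds for every phantom mask", {
  for (seed in 1:5) {
    m <- make_test_phantom(seed)$label
    expect_equal(cldice_score(m, m), 1)
    cc <- confusion_counts(m, m)
    expect_equal(dice_score(cc), 1)
    expect_equal(iou_score(cc), 1)
  }
})

test_that("evaluate composes the individual metrics", {
  ph <- make_test_phantom(61L)
  soft <- soft_mask(ph$label$voxels, ph$label$spacing)
  rep <- evaluate(soft, ph$label)
  expect_equal(rep$dice, 1)
  expect_equal(rep$iou, 1)
  expect_equal(rep$cldice, 1)
  expect_equal(rep$hd95_mm, 0)

  # prediction distinct from the reference: fields equal the parts
  pred <- soft_mask(pmin(pmax(ph$label$voxels * 0.8 +
                                array(runif(prod(ph$label$shape)), ph$label$shape) * 0.3,
                              0), 1), ph$label$spacing)
  rep2 <- evaluate(pred, ph$label, threshold = 0.5)
  pb <- binary_mask(array(as.numeric(pred$voxels >= 0.5), pred$shape))
  cc <- confusion_counts(pb, ph$label)
  expect_equal(rep2$dice, dice_score(cc))
  expect_equal(rep2$iou, iou_score(cc))
  expect_equal(rep2$cldice, cldice_score(pb, ph$label))
  expect_equal(rep2$hd_mm, hausdorff(pb, ph$label, 100))
  expect_equal(rep2$hd95_mm, hausdorff(pb, ph$label, 95))

  # degenerate threshold: empty prediction, distances flagged undefined
  rep3 <- evaluate(soft, ph$label, threshold = 1.1)
  expect_equal(rep3$dice, 0)
  expect_true(rep3$undefined_distances)
  expect_true(is.na(rep3$hd95_mm))

  # JSON report round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep2, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$dice, rep2$dice, tolerance = 1e-12)
})
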