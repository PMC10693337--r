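test_that("soft skeletonization thins masks without leaving their support", {
  expect_equal(sum(soft_skeleton(array(0, c(6, 6, 6)), 3)), 0)

  # a 1-voxel-thick line is its own skeleton: opening removes it entirely
  lp <- line_pair()
  sk <- soft_skeleton(lp$ref, 5)
  expect_identical(sk, lp$ref)

  # a solid cube thins strictly
  cube <- array(0, c(9, 9, 9))
  cube[3:7, 3:7, 3:7] <- 1
  sk2 <- soft_skeleton(cube, 2)
  expect_true(all(sk2[cube == 0] == 0))
  expect_lt(sum(sk2), sum(cube))
  expect_gt(sum(sk2), 0)

  # voxel count is non-increasing in the iteration count on binary input
  ph <- make_test_phantom(51L)
  counts <- vapply(1:6, function(k) sum(soft_skeleton(ph$label$voxels, k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 1e-9))

  expect_error(soft_skeleton(cube, 0), ">= 1")
})

test_that("soft Dice loss matches its defining ratio", {
  set.seed(0)
  p <- array(runif(64), c(4, 4, 4))
  t <- array(as.numeric(runif(64) < 0.5), c(4, 4, 4))
  eps <- 1e-6
  want <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  expect_equal(dice_loss(p, t, eps), want, tolerance = 1e-12)

  expect_lt(dice_loss(t, t), 1e-6)
  expect_gt(dice_loss(array(0, dim(t)), t), 1 - 1e-4)
  expect_error(dice_loss(array(0.5, c(3, 3, 3)), t), "shape mismatch")
})

test_that("the centerline-Dice worked example gives exactly one third", {
  lp <- line_pair()
  # skeletons of 1-voxel lines are the lines themselves, so
  # Tprec = |pred line in ref| / |pred line| = 1,
  # Tsens = |ref line in pred| / |ref line| = 5/10,
  # clDice = 2 * 1 * 0.5 / 1.5 = 2/3, loss = 1/3
  loss <- cldice_loss(lp$pred, lp$ref, k = 5)
  expect_equal(loss, 1 / 3, tolerance = 1e-5)
  expect_lt(cldice_loss(lp$ref, lp$ref, k = 5), 1e-5)
})

test_that("a mid-tube gap is penalized more by clDice than by Dice", {
  tube <- straight_tube(c(28L, 11L, 11L), 5, 24, c(6, 6), 2)
  gapped <- tube
  gapped[14:15, , ] <- 0
  lc <- cldice_loss(gapped, tube, k = 5)
  ld <- dice_loss(gapped, tube)
  expect_gt(lc, 0)
  expect_gt(lc / ld, 1)
  expect_lt(cldice_loss(tube, tube, k = 5), 1e-5)
})

test_that("the total loss interpolates its two terms exactly", {
  set.seed(2)
  p <- array(runif(8^3), c(8, 8, 8))
  t <- array(as.numeric(runif(8^3) < 0.1), c(8, 8, 8))
  expect_identical(total_loss(p, t, loss_config(lambda = 0)),
                   dice_loss(p, t))
  expect_identical(total_loss(p, t, loss_config(lambda = 1)),
                   cldice_loss(p, t, k = 5))

  # the worked line example at lambda = 0.1:
  # L_Dice = 1 - 10/15 = 1/3 and L_clDice = 1/3, so the total is 1/3
  lp <- line_pair()
  tot <- total_loss(lp$pred, lp$ref, loss_config(lambda = 0.1))
  expect_equal(as.numeric(tot), 1 / 3, tolerance = 1e-5)

  # affine in lambda for fixed inputs
  ld <- dice_loss(p, t)
  lc <- cldice_loss(p, t)
  for (lam in c(0.2, 0.5, 0.8))
    expect_equal(as.numeric(total_loss(p, t, loss_config(lambda = lam))),
                 (1 - lam) * ld + lam * lc, tolerance = 1e-12)

  expect_error(loss_config(lambda = 1.5), "\\[0, 1\\]")
})

test_that("losses stay within [0, 1] on random mask pairs", {
  set.seed(4)
  for (i in 1:25) {
    pr <- random_mask_pair(c(6, 6, 6))
    soft <- array(runif(216), c(6, 6, 6))
    for (v in c(dice_loss(soft, pr$b), cldice_loss(soft, pr$b, k = 3),
                as.numeric(total_loss(soft, pr$b, loss_config(0.3, 3L))))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("loss gradients with respect to the prediction are finite and nonzero", {
  set.seed(6)
  p <- canalseg:::ag_node(array(runif(6^3, 0.05, 0.95), c(6, 6, 6)))
  t <- straight_tube(c(6L, 6L, 6L), 2, 5, c(3, 3), 1.5)
  loss <- total_loss(p, t, loss_config(lambda = 0.1, skeleton_iters = 3L))
  canalseg:::ag_backward(loss)
  expect_true(all(is.finite(p$grad)))
  expect_gt(max(abs(p$grad)), 0)

  # finite-difference check on a few voxels
  f <- function(x) as.numeric(total_loss(x, t, loss_config(0.1, 3L)))
  base <- p$value
  for (i in c(1L, 100L, 200L)) {
    xp <- base; xp[i] <- xp[i] + 1e-6
    xm <- base; xm[i] <- xm[i] - 1e-6
    num <- (f(xp) - f(xm)) / 2e-6
    expect_equal(p$grad[i], num, tolerance = 1e-4)
  }
})

test_that("cross-entropy matches its definition and is differentiable", {
  set.seed(9)
  p <- array(runif(4^3, 0.05, 0.95), c(4, 4, 4))
  t <- array(as.numeric(runif(4^3) < 0.4), c(4, 4, 4))
  eps <- 1e-6
  want <- -mean(t * log(p + eps) + (1 - t) * log(1 - p + eps))
  expect_equal(bce_loss(p, t), want, tolerance = 1e-12)

  node <- canalseg:::ag_node(p)
  loss <- bce_loss(node, t)
  canalseg:::ag_backward(loss)
  i <- 7L
  pp <- p; pp[i] <- pp[i] + 1e-7
  pm <- p; pm[i] <- pm[i] - 1e-7
  expect_equal(node$grad[i], (bce_loss(pp, t) - bce_loss(pm, t)) / 2e-7,
               tolerance = 1e-5)
})
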