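tiny <- model_config("tiny")

test_that("forward passes respect shape, range and seeding contracts", {
  m <- build_model(tiny, seed = 1)
  set.seed(1)
  patch <- array(runif(32^3), c(32, 32, 32))
  y <- model_forward(m, patch)
  expect_equal(dim(y), c(32L, 32L, 32L))
  expect_gt(min(y), 0)
  expect_lt(max(y), 1)

  # identical seeds give identical parameters and outputs
  m2 <- build_model(tiny, seed = 1)
  expect_identical(m$P[["stem.w"]]$value, m2$P[["stem.w"]]$value)
  expect_identical(y, model_forward(m2, patch))
  # a different seed gives different parameters
  m3 <- build_model(tiny, seed = 2)
  expect_false(identical(m$P[["stem.w"]]$value, m3$P[["stem.w"]]$value))

  expect_error(model_forward(m, array(0.5, c(31, 32, 32))), "divisible by 32")
})

test_that("the encoder/decoder grid cascade matches five halvings", {
  m <- build_model(tiny, seed = 1)
  s <- model_summary(m, patch = 96L)
  expect_equal(s$grid[s$stage == "bottleneck"], "3^3")
  expect_equal(s$grid[s$stage == "stage1"], "48^3")
  s32 <- model_summary(m, patch = 32L)
  expect_equal(s32$grid[s32$stage == "bottleneck"], "1^3")
  expect_equal(s32$channels[s32$stage == "bottleneck"],
               tiny$base_embed_dim * 16)
  expect_gt(attr(s, "n_parameters"), 0)
})

test_that("the DRC block is the sum of its two branches", {
  mod <- drc_module(4L, 6L, seed = 3)
  set.seed(3)
  x <- array(rnorm(4 * 8 * 8 * 8), c(4, 8, 8, 8))

  # spatial extent is preserved, channels projected
  y <- drc_forward(mod, x)
  expect_equal(dim(y), c(6L, 8L, 8L, 8L))

  # zero input with zero biases/offsets gives zero output
  y0 <- drc_forward(mod, array(0, c(4, 8, 8, 8)))
  expect_equal(max(abs(y0)), 0)

  # zeroing the right branch's last convolution leaves the left branch alone
  mod2 <- drc_module(4L, 6L, seed = 3)
  mod2$P[["drc.r3.w"]]$value[] <- 0
  y_left_only <- drc_forward(mod2, x)
  # left branch computed independently: 1x1 conv = channel matmul, then
  # instance norm and ReLU
  W <- mod$P[["drc.l1.w"]]$value
  b <- mod$P[["drc.l1.b"]]$value
  xm <- matrix(x, 4, 512)
  l <- W %*% xm + b
  mu <- rowMeans(l)
  sdv <- sqrt(rowMeans((l - mu)^2) + 1e-5)
  l <- (l - mu) / sdv
  l[l < 0] <- 0
  expect_equal(y_left_only, array(l, c(6, 8, 8, 8)), tolerance = 1e-12)

  expect_error(drc_forward(mod, array(0, c(3, 8, 8, 8))), "channels")
})

test_that("pixel-level fusion upsamples, projects and adds", {
  mod <- drc_module(8L, 4L, seed = 5)
  set.seed(5)
  f_n <- array(rnorm(4 * 16^3), c(4, 16, 16, 16))
  f_prev <- array(rnorm(8 * 8^3), c(8, 8, 8, 8))
  fused <- fuse_features(mod, f_n, f_prev)
  expect_equal(dim(fused), c(4L, 16L, 16L, 16L))

  # coarser input of zeros is the additive identity
  fused0 <- fuse_features(mod, f_n, array(0, c(8, 8, 8, 8)))
  expect_equal(fused0, f_n)

  expect_error(fuse_features(mod, f_n, array(0, c(8, 4, 4, 4))),
               "incompatible")
})

test_that("fusion ablations change the decoder output", {
  set.seed(2)
  patch <- array(runif(32^3), c(32, 32, 32))
  outs <- lapply(c("none", "plain_conv", "drc"), function(f) {
    m <- build_model(model_config("tiny", fusion = f), seed = 1)
    model_forward(m, patch)
  })
  expect_false(identical(outs[[1]], outs[[3]]))
  expect_false(identical(outs[[2]], outs[[3]]))
})

test_that("a single optimizer step decreases the training loss", {
  ph <- make_test_phantom(71L)
  m <- build_model(tiny, seed = 1)
  cfg <- train_config("tiny", epochs = 2L, seed = 1, fg_patch_bias = 1)
  r <- train(m, list(list(volume = ph$volume, label = ph$label)), cfg,
             loss_config(lambda = 0.1))
  expect_lt(r$log$loss[2], r$log$loss[1])
})

test_that("checkpoints round-trip the model exactly", {
  tmp <- withr::local_tempdir()
  m <- build_model(tiny, seed = 4)
  set.seed(9)
  patch <- array(runif(32^3), c(32, 32, 32))
  y <- model_forward(m, patch)
  save_checkpoint(m, file.path(tmp, "ck.rds"))
  expect_true(file.exists(file.path(tmp, "ck.rds.json")))
  m2 <- load_checkpoint(file.path(tmp, "ck.rds"))
  expect_identical(model_forward(m2, patch), y)
})
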