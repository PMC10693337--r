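# Training, sliding-window inference, and pseudo-label fusion.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with beta1 = 0.99 (its
#' "momentum"), initial learning rate 1e-4 annealed to zero on a cosine
#' schedule, batch size 1, 500 epochs over the training set, 96^3 patches.
#' The tiny preset keeps the protocol but runs 30 epochs on 32^3 patches.
#'
#' @param preset "default" or "tiny".
#' @param lr,beta1,beta2 Adam hyper-parameters. The default learning rate is
#'   1e-4 (full protocol); the tiny preset defaults to 1e-3, compensating for
#'   its roughly 60-fold shorter optimization schedule.
#' @param epochs Number of passes over the training set.
#' @param patch Cubic patch edge (divisible by 32).
#' @param patches_per_volume Patches sampled per volume per epoch.
#' @param fg_patch_bias Fraction of patches centred on a random foreground
#'   voxel (the rest are uniform); counteracts <2% foreground prevalence.
#' @param schedule "cosine" or "constant".
#' @param seed Seed for patch sampling.
#' @return A `train_config` object.
#' @export
train_config <- function(preset = c("default", "tiny"), lr = NULL,
                         beta1 = 0.99, beta2 = 0.999, epochs = NULL,
                         patch = NULL, patches_per_volume = 1L,
                         fg_patch_bias = 0.5,
                         schedule = c("cosine", "constant"), seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(lr)) lr <- if (preset == "tiny") 1e-3 else 1e-4
  if (is.null(epochs)) epochs <- if (preset == "tiny") 30L else 500L
  if (is.null(patch)) patch <- if (preset == "tiny") 32L else 96L
  structure(list(preset = preset, lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = 1L, epochs = as.integer(epochs),
                 patch = as.integer(patch),
                 patches_per_volume = as.integer(patches_per_volume),
                 fg_patch_bias = fg_patch_bias,
                 schedule = match.arg(schedule), seed = as.integer(seed)),
            class = "train_config")
}

#' Inference configuration
#'
#' @param window Cubic sliding-window edge (default 96).
#' @param stride Window stride (default 48, i.e. 50% overlap).
#' @param blend Overlap blending: "mean" or "gaussian".
#' @param threshold Binarization threshold for downstream evaluation.
#' @return An `infer_config` object.
#' @export
infer_config <- function(window = 96L, stride = 48L,
                         blend = c("mean", "gaussian"), threshold = 0.5) {
  if (stride > window) stop("stride must not exceed window")
  structure(list(window = as.integer(window), stride = as.integer(stride),
                 blend = match.arg(blend), threshold = threshold),
            class = "infer_config")
}

#' Label-fusion configuration
#'
#' @param alpha Weight of the pseudo-label in the convex combination.
#' @param threshold Binarization threshold of the fused soft label. At the
#'   default (0.6 with alpha 0.5) the pseudo-label acts as a weak veto: a
#'   circular-expansion voxel survives only with pseudo-probability of at
#'   least 0.2, and voxels outside the expansion are never added.
#' @param keep_largest_component Retain only the largest 26-connected
#'   component of the fused mask.
#' @return A `fusion_config` object.
#' @export
fusion_config <- function(alpha = 0.5, threshold = 0.6,
                          keep_largest_component = TRUE) {
  if (alpha < 0 || alpha > 1 || threshold < 0 || threshold > 1)
    stop("alpha and threshold must lie in [0, 1]")
  structure(list(alpha = alpha, threshold = threshold,
                 keep_largest_component = keep_largest_component),
            class = "fusion_config")
}

# foreground-biased cubic patch sampling; `fg` is the precomputed 0-based
# foreground coordinate matrix of the label
sample_patch <- function(vol, lab, patch, fg_bias, rng, fg) {
  sh <- vol$shape
  if (any(sh < patch)) stop("volume smaller than the training patch")
  use_fg <- nrow(fg) > 0 && rng$runif(1) < fg_bias
  lo <- integer(3)
  for (j in 1:3) {
    if (use_fg) {
      centre <- fg[ceiling(rng$runif(1) * nrow(fg)), j]
      lo[j] <- min(max(centre - patch %/% 2L, 0L), sh[j] - patch)
    } else {
      lo[j] <- floor(rng$runif(1) * (sh[j] - patch + 1))
    }
  }
  rs <- lapply(1:3, function(j) (lo[j] + 1):(lo[j] + patch))
  list(v = vol$voxels[rs[[1]], rs[[2]], rs[[3]]],
       l = lab$voxels[rs[[1]], rs[[2]], rs[[3]]])
}

#' Train a segmentation model
#'
#' Seeded, reproducible single-sample training with foreground-biased patch
#' sampling, Adam, and cosine learning-rate annealing. Aborts on NaN loss.
#'
#' @param model A `canal_model` (mutated in place and returned).
#' @param dataset List of `list(volume, label)` pairs, geometry-aligned.
#' @param cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param out_dir Optional directory for `checkpoint.rds` and
#'   `train_log.csv`.
#' @return A list: `model`, `log` (data.frame epoch / loss / dice / cldice /
#'   lr).
#' @export
train <- function(model, dataset, cfg = train_config("tiny"),
                  loss_cfg = loss_config(), out_dir = NULL) {
  stopifnot(inherits(model, "canal_model"), inherits(cfg, "train_config"))
  if (length(dataset) == 0) stop("empty training dataset")
  mult <- required_multiple(model$config)
  if (cfg$patch %% mult != 0)
    stop(sprintf("patch edge %d must be divisible by %d", cfg$patch, mult))
  for (pair in dataset) check_aligned(pair$volume, pair$label)
  fg_cache <- lapply(dataset, function(p)
    which(p$label$voxels == 1, arr.ind = TRUE) - 1L)
  # volumes no larger than the patch always yield the whole label, so the
  # reference soft skeleton can be computed once per volume
  skel_cache <- lapply(dataset, function(p) {
    if (all(p$volume$shape == cfg$patch) && loss_cfg$lambda > 0)
      soft_skeleton(p$label$voxels, loss_cfg$skeleton_iters)
    else NULL
  })
  rng <- local_rng(cfg$seed)
  opt <- new.env(parent = emptyenv())
  # m and v are updated in place by the compiled Adam step, so each needs
  # its own freshly allocated buffers
  opt$m <- lapply(model$P, function(p) p$value * 0)
  opt$v <- lapply(model$P, function(p) p$value * 0)
  opt$t <- 0
  log <- vector("list", cfg$epochs)
  lam <- loss_cfg$lambda
  for (epoch in seq_len(cfg$epochs)) {
    lr_t <- if (cfg$schedule == "cosine")
      cfg$lr * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$epochs)) else cfg$lr
    order_idx <- rng$sample(length(dataset), length(dataset))
    losses <- c(); dices <- c()
    for (vi in order_idx) {
      pair <- dataset[[vi]]
      for (rep_i in seq_len(cfg$patches_per_volume)) {
        pt <- sample_patch(pair$volume, pair$label, cfg$patch,
                           cfg$fg_patch_bias, rng, fg_cache[[vi]])
        out <- model_forward(model, pt$v, tracked = TRUE)
        pred <- ag_reshape(out, dim(pt$l))
        loss <- total_loss(pred, pt$l, loss_cfg, skel_cache[[vi]])
        lval <- as.numeric(loss$value)
        if (!is.finite(lval))
          stop(sprintf("non-finite loss at epoch %d (volume %d); aborting",
                       epoch, vi))
        ag_backward(loss)
        opt$t <- opt$t + 1
        c1 <- 1 / (1 - cfg$beta1^opt$t)
        c2 <- 1 / (1 - cfg$beta2^opt$t)
        for (nm in names(model$P)) {
          p <- model$P[[nm]]
          if (is.null(p$grad)) next
          cs_adam_step(p$value, p$grad, opt$m[[nm]], opt$v[[nm]], lr_t,
                       cfg$beta1, cfg$beta2, c1, c2, 1e-8)
          p$grad <- NULL
        }
        losses <- c(losses, lval)
        pv <- ag_value(pred)
        eps <- loss_cfg$epsilon
        dices <- c(dices, 1 - (2 * sum(pv * pt$l) + eps) /
                     (sum(pv) + sum(pt$l) + eps))
      }
    }
    ld <- mean(dices)
    lc <- if (lam > 0) (mean(losses) - (1 - lam) * ld) / lam else NA_real_
    log[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses),
                               dice_loss = ld, cldice_loss = lc, lr = lr_t)
    cs_log("debug", "epoch %d/%d loss %.4f", epoch, cfg$epochs, mean(losses))
  }
  log <- do.call(rbind, log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
    utils::write.csv(log, file.path(out_dir, "train_log.csv"),
                     row.names = FALSE)
  }
  list(model = model, log = log)
}

pad_to_window <- function(arr, window) {
  sh <- dim(arr)
  pad <- pmax(window - sh, 0)
  if (all(pad == 0)) return(list(arr = arr, pad = pad))
  out <- array(0, sh + pad)
  out[1:sh[1], 1:sh[2], 1:sh[3]] <- arr
  # replicate edges into the padding
  if (pad[1] > 0) out[(sh[1] + 1):(sh[1] + pad[1]), , ] <-
      out[rep(sh[1], pad[1]), , ]
  if (pad[2] > 0) out[, (sh[2] + 1):(sh[2] + pad[2]), ] <-
      out[, rep(sh[2], pad[2]), ]
  if (pad[3] > 0) out[, , (sh[3] + 1):(sh[3] + pad[3])] <-
      out[, , rep(sh[3], pad[3])]
  list(arr = out, pad = pad)
}

window_starts <- function(n, window, stride) {
  s <- seq(0L, max(n - window, 0L), by = stride)
  if (s[length(s)] + window < n) s <- c(s, n - window)
  s
}

#' Sliding-window inference
#'
#' Tiles the volume into overlapping cubic windows, predicts each, and
#' blends overlaps (unweighted mean by default, Gaussian-weighted behind a
#' flag). Volumes smaller than one window are edge-padded and un-padded.
#'
#' @param model A `canal_model`, or any function mapping a 3D patch array to
#'   an equally-shaped array (useful for stitching diagnostics).
#' @param vol An [intensity_volume()].
#' @param cfg An [infer_config()].
#' @return A [soft_mask()] aligned with `vol`.
#' @export
sliding_window_infer <- function(model, vol, cfg = infer_config()) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(cfg, "infer_config"))
  fwd <- if (is.function(model)) model else
    function(patch) model_forward(model, patch, tracked = FALSE)
  padded <- pad_to_window(vol$voxels, cfg$window)
  arr <- padded$arr
  sh <- dim(arr)
  acc <- array(0, sh)
  wsum <- array(0, sh)
  wpatch <- if (cfg$blend == "mean") array(1, rep(cfg$window, 3)) else {
    x <- seq_len(cfg$window) - (cfg$window + 1) / 2
    g1 <- exp(-x^2 / (2 * (0.125 * cfg$window)^2))
    outer(outer(g1, g1), g1)
  }
  dim(wpatch) <- rep(cfg$window, 3)
  for (sw in window_starts(sh[3], cfg$window, cfg$stride))
    for (sh2 in window_starts(sh[2], cfg$window, cfg$stride))
      for (sd in window_starts(sh[1], cfg$window, cfg$stride)) {
        rs <- list((sd + 1):(sd + cfg$window), (sh2 + 1):(sh2 + cfg$window),
                   (sw + 1):(sw + cfg$window))
        pred <- fwd(arr[rs[[1]], rs[[2]], rs[[3]]])
        acc[rs[[1]], rs[[2]], rs[[3]]] <-
          acc[rs[[1]], rs[[2]], rs[[3]]] + pred * wpatch
        wsum[rs[[1]], rs[[2]], rs[[3]]] <-
          wsum[rs[[1]], rs[[2]], rs[[3]]] + wpatch
      }
  out <- acc / wsum
  out <- out[1:vol$shape[1], 1:vol$shape[2], 1:vol$shape[3], drop = FALSE]
  soft_mask(pmin(pmax(out, 0), 1), vol$spacing, vol$origin)
}

#' Deep label fusion
#'
#' Combines a model's pseudo-label (rich semantics, possibly broken
#' connectivity) with a circular-expansion label (clean boundaries) by a
#' convex voxelwise combination, thresholding, and optional
#' largest-component cleanup.
#'
#' @param pseudo A [soft_mask()] predicted on a sparsely annotated volume.
#' @param circ The [binary_mask()] circular-expansion label.
#' @param cfg A [fusion_config()].
#' @return The fused [binary_mask()].
#' @export
deep_label_fusion <- function(pseudo, circ, cfg = fusion_config()) {
  stopifnot(inherits(circ, "binary_mask"), inherits(cfg, "fusion_config"))
  check_aligned(pseudo, circ)
  if (sum(pseudo$voxels) == 0 && sum(circ$voxels) == 0)
    stop("both fusion inputs are empty")
  fused_soft <- cfg$alpha * pseudo$voxels + (1 - cfg$alpha) * circ$voxels
  fused <- array(as.numeric(fused_soft >= cfg$threshold), dim(fused_soft))
  if (cfg$keep_largest_component && sum(fused) > 0)
    fused <- largest_component(fused)
  binary_mask(fused, circ$spacing, circ$origin)
}

#' Two-stage training with fused pseudo-labels
#'
#' Stage 1 trains a model on densely annotated pairs. Stage 2 predicts
#' pseudo-labels on the sparsely annotated volumes and fuses them with
#' their circular-expansion labels ([deep_label_fusion()]). Stage 3
#' pre-trains a fresh model on the fused pairs, and stage 4 fine-tunes it
#' on the dense pairs. All stages are seeded.
#'
#' @param dense_set List of `list(volume, label)` densely annotated pairs.
#' @param sparse_set List of `list(volume, circ)` pairs: volume plus its
#'   circular-expansion label.
#' @param model_cfg A [model_config()].
#' @param stage1_cfg,pretrain_cfg,finetune_cfg [train_config()]s for the
#'   dense stage-1 run, fused pre-training, and dense fine-tuning.
#' @param loss_cfg A [loss_config()].
#' @param fusion_cfg A [fusion_config()].
#' @param infer_cfg An [infer_config()] for pseudo-label prediction.
#' @param seed Master seed (stage seeds are derived from it).
#' @param out_dir Optional output directory (two checkpoints + fusion masks).
#' @return List: `model` (final), `stage1_model`, `pseudo` (soft masks),
#'   `fused` (binary masks), `logs`.
#' @export
pretrain_then_finetune <- function(dense_set, sparse_set,
                                   model_cfg = model_config("tiny"),
                                   stage1_cfg = train_config("tiny"),
                                   pretrain_cfg = stage1_cfg,
                                   finetune_cfg = stage1_cfg,
                                   loss_cfg = loss_config(),
                                   fusion_cfg = fusion_config(),
                                   infer_cfg = infer_config(32L, 16L),
                                   seed = 1L, out_dir = NULL) {
  if (length(dense_set) == 0) stop("dense_set must be nonempty")
  if (length(sparse_set) == 0) stop("sparse_set must be nonempty")
  seed <- as.integer(seed)
  cs_log("info", "stage 1: training on %d dense pairs", length(dense_set))
  m1 <- build_model(model_cfg, seed = seed)
  stage1_cfg$seed <- seed + 11L
  r1 <- train(m1, dense_set, stage1_cfg, loss_cfg)
  cs_log("info", "stage 2: pseudo-labelling %d sparse volumes",
         length(sparse_set))
  pseudo <- lapply(sparse_set, function(p)
    sliding_window_infer(r1$model, p$volume, infer_cfg))
  fused <- mapply(function(ps, p) deep_label_fusion(ps, p$circ, fusion_cfg),
                  pseudo, sparse_set, SIMPLIFY = FALSE)
  cs_log("info", "stage 3: pre-training a fresh model on fused labels")
  m2 <- build_model(model_cfg, seed = seed + 1L)
  pre_set <- mapply(function(p, f) list(volume = p$volume, label = f),
                    sparse_set, fused, SIMPLIFY = FALSE)
  pretrain_cfg$seed <- seed + 22L
  r2 <- train(m2, pre_set, pretrain_cfg, loss_cfg)
  cs_log("info", "stage 4: fine-tuning on dense pairs")
  finetune_cfg$seed <- seed + 33L
  r3 <- train(r2$model, dense_set, finetune_cfg, loss_cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(r1$model, file.path(out_dir, "stage1.rds"))
    save_checkpoint(r3$model, file.path(out_dir, "final.rds"))
    for (i in seq_along(fused))
      write_mask(fused[[i]], file.path(out_dir, sprintf("fused_%03d.nii.gz", i)))
  }
  list(model = r3$model, stage1_model = r1$model, pseudo = pseudo,
       fused = fused,
       logs = list(stage1 = r1$log, pretrain = r2$log, finetune = r3$log))
}
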