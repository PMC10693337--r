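# Segmentation network: a 4-stage shifted-window transformer encoder over
# 3D patches, a U-shaped convolutional decoder, and pixel-level feature
# fusion between decoder levels through deep residual convolution (DRC)
# blocks. The stem halves the grid; each of the four stages ends in a
# patch-merging downsampling, so a patch edge must be divisible by 2^5 and
# the decoder restores it through five successive x2 upsamplings.

#' Model configuration
#'
#' @param preset "default" (embed 48, window 6 — the full-scale protocol for
#'   96^3 patches) or "tiny" (embed 8, window 2 — the same architecture at
#'   CPU scale for 32^3 patches).
#' @param base_embed_dim Embedding width of stage 1; stage i uses
#'   `base_embed_dim * 2^(i-1)` channels.
#' @param window_size Attention window edge in tokens; clamped per stage to
#'   the largest value that tiles the stage grid.
#' @param fusion Pixel-level decoder fusion: `"drc"` (default), a plain
#'   convolution block (`"plain_conv"`), or `"none"` (the plain U-decoder
#'   baseline).
#' @param n_stages Number of transformer stages (4).
#' @param in_channels,out_channels Input/output channels (1).
#' @param patch_size Stem downsampling factor (2).
#' @param mlp_ratio Hidden-width multiple of the transformer MLPs.
#' @return A `model_config` object.
#' @export
model_config <- function(preset = c("default", "tiny"),
                         base_embed_dim = NULL, window_size = NULL,
                         fusion = c("drc", "plain_conv", "none"),
                         n_stages = 4L, in_channels = 1L, out_channels = 1L,
                         patch_size = 2L, mlp_ratio = 4) {
  preset <- match.arg(preset)
  fusion <- match.arg(fusion)
  if (is.null(base_embed_dim))
    base_embed_dim <- if (preset == "tiny") 8L else 48L
  if (is.null(window_size)) window_size <- if (preset == "tiny") 2L else 6L
  structure(list(preset = preset, base_embed_dim = as.integer(base_embed_dim),
                 window_size = as.integer(window_size), fusion = fusion,
                 n_stages = as.integer(n_stages),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 patch_size = as.integer(patch_size), mlp_ratio = mlp_ratio),
            class = "model_config")
}

required_multiple <- function(cfg) as.integer(2^(cfg$n_stages + 1))

# --- parameter registry -----------------------------------------------------

mk_registry <- function(rng) {
  P <- list()
  reg <- function(name, value) {
    P[[name]] <<- ag_node(value)
    invisible(NULL)
  }
  lin <- function(name, n_in, n_out) {
    reg(paste0(name, ".w"), matrix(rng$rnorm(n_in * n_out, sd = 0.02),
                                   n_in, n_out))
    reg(paste0(name, ".b"), numeric(n_out))
  }
  conv <- function(name, cin, cout, k) {
    fan <- cin * k^3
    reg(paste0(name, ".w"), matrix(rng$rnorm(cout * fan, sd = sqrt(2 / fan)),
                                   cout, fan))
    reg(paste0(name, ".b"), numeric(cout))
  }
  norm <- function(name, C) {
    reg(paste0(name, ".g"), rep(1, C))
    reg(paste0(name, ".be"), numeric(C))
  }
  list(reg = reg, lin = lin, conv = conv, norm = norm, get = function() P)
}

drc_mid <- function(cout) max(cout %/% 2L, 1L)

register_drc <- function(r, name, cin, cout) {
  mid <- drc_mid(cout)
  r$conv(paste0(name, ".l1"), cin, cout, 1L)
  r$norm(paste0(name, ".l1n"), cout)
  r$conv(paste0(name, ".r1"), cin, mid, 1L)
  r$norm(paste0(name, ".r1n"), mid)
  r$conv(paste0(name, ".r2"), mid, mid, 3L)
  r$norm(paste0(name, ".r2n"), mid)
  r$conv(paste0(name, ".r3"), mid, cout, 1L)
  r$norm(paste0(name, ".r3n"), cout)
}

register_block <- function(r, name, C, ratio) {
  r$norm(paste0(name, ".ln1"), C)
  for (nm in c("q", "k", "v", "o")) r$lin(paste0(name, ".", nm), C, C)
  r$norm(paste0(name, ".ln2"), C)
  hidden <- as.integer(round(ratio * C))
  r$lin(paste0(name, ".m1"), C, hidden)
  r$lin(paste0(name, ".m2"), hidden, C)
}

register_conv_in <- function(r, name, cin, cout, k) {
  r$conv(name, cin, cout, k)
  r$norm(paste0(name, "n"), cout)
}

#' Build a segmentation model
#'
#' Parameters are initialized deterministically from `seed`; the same
#' config and seed always give identical parameters.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `canal_model` object (config + named parameter set).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  rng <- local_rng(seed)
  r <- mk_registry(rng)
  F0 <- config$base_embed_dim
  dims <- F0 * 2^(0:(config$n_stages))  # stage dims + bottleneck

  register_conv_in(r, "stem", config$in_channels, F0, 2L)
  for (i in seq_len(config$n_stages)) {
    C <- dims[i]
    register_block(r, sprintf("s%d.b1", i), C, config$mlp_ratio)
    register_block(r, sprintf("s%d.b2", i), C, config$mlp_ratio)
    r$norm(sprintf("s%d.mln", i), 8L * C)
    r$lin(sprintf("s%d.merge", i), 8L * C, 2L * C)
  }
  # decoder: five x2 upsamplings from the bottleneck back to full resolution
  for (i in config$n_stages:1) {
    cin <- dims[i + 1]; cout <- dims[i]
    register_conv_in(r, sprintf("d%d.up", i), cin, cout, 3L)
    mid <- max(cout %/% 2L, 4L)
    register_conv_in(r, sprintf("d%d.c1", i), 2L * cout, mid, 3L)
    register_conv_in(r, sprintf("d%d.c2", i), mid, cout, 3L)
    r$conv(sprintf("d%d.proj", i), 2L * cout, cout, 1L)
    if (config$fusion == "drc") {
      register_drc(r, sprintf("d%d.fuse", i), cin, cout)
    } else if (config$fusion == "plain_conv") {
      register_conv_in(r, sprintf("d%d.fuse", i), cin, cout, 3L)
    }
  }
  register_conv_in(r, "d0.up", F0, F0, 1L)
  r$conv("head", F0, config$out_channels, 1L)

  structure(list(config = config, P = r$get(), seed = as.integer(seed)),
            class = "canal_model")
}

#' @export
print.canal_model <- function(x, ...) {
  cat(sprintf("<canal_model preset=%s embed=%d window=%d fusion=%s, %d parameters>\n",
              x$config$preset, x$config$base_embed_dim, x$config$window_size,
              x$config$fusion, n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model A `canal_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$P, function(p) length(p$value), numeric(1)))
}

# --- forward building blocks ------------------------------------------------

lin_fwd <- function(P, name, x)
  ag_addvec_rows(ag_matmul(x, P[[paste0(name, ".w")]]), P[[paste0(name, ".b")]])

conv_in_relu <- function(P, name, x, k, stride = 1L) {
  y <- ag_conv3d(x, P[[paste0(name, ".w")]], P[[paste0(name, ".b")]], k,
                 stride, if (stride == 1L) (k - 1L) %/% 2L else 0L)
  ag_innorm_relu(y, P[[paste0(name, "n.g")]], P[[paste0(name, "n.be")]])
}

drc_fwd <- function(P, name, x) {
  left <- ag_innorm_relu(
    ag_conv3d(x, P[[paste0(name, ".l1.w")]], P[[paste0(name, ".l1.b")]], 1L),
    P[[paste0(name, ".l1n.g")]], P[[paste0(name, ".l1n.be")]])
  right <- ag_innorm_relu(
    ag_conv3d(x, P[[paste0(name, ".r1.w")]], P[[paste0(name, ".r1.b")]], 1L),
    P[[paste0(name, ".r1n.g")]], P[[paste0(name, ".r1n.be")]])
  right <- ag_innorm_relu(
    ag_conv3d(right, P[[paste0(name, ".r2.w")]], P[[paste0(name, ".r2.b")]], 3L),
    P[[paste0(name, ".r2n.g")]], P[[paste0(name, ".r2n.be")]])
  right <- ag_innorm_relu(
    ag_conv3d(right, P[[paste0(name, ".r3.w")]], P[[paste0(name, ".r3.b")]], 1L),
    P[[paste0(name, ".r3n.g")]], P[[paste0(name, ".r3n.be")]])
  ag_add(left, right)
}

# window-partition permutation for a token grid `g`, window `ws`, cyclic
# shift `s`: output rows are ordered within-window-first, windows after.
win_perm <- function(g, ws, s) {
  nw <- g %/% ws
  wd <- rep(0:(nw[1] - 1), times = nw[2] * nw[3])
  wh <- rep(rep(0:(nw[2] - 1), each = nw[1]), times = nw[3])
  ww <- rep(0:(nw[3] - 1), each = nw[1] * nw[2])
  id <- rep(0:(ws - 1), times = ws * ws)
  ih <- rep(rep(0:(ws - 1), each = ws), times = ws)
  iw <- rep(0:(ws - 1), each = ws * ws)
  Tw <- ws^3
  nW <- prod(nw)
  d <- rep(wd, each = Tw) * ws + rep(id, times = nW)
  h <- rep(wh, each = Tw) * ws + rep(ih, times = nW)
  w <- rep(ww, each = Tw) * ws + rep(iw, times = nW)
  sd <- (d + s) %% g[1]
  sh <- (h + s) %% g[2]
  sw <- (w + s) %% g[3]
  1L + sd + g[1] * (sh + g[2] * sw)
}

swin_block <- function(P, name, x, g, ws, shift, heads) {
  C <- ncol(ag_value(x))
  dh <- C %/% heads
  h1 <- ag_layernorm(x, P[[paste0(name, ".ln1.g")]],
                     P[[paste0(name, ".ln1.be")]])
  perm <- win_perm(g, ws, shift)
  inv <- order(perm)
  Tw <- ws^3
  nW <- length(perm) %/% Tw
  B <- nW * heads
  to_batched <- function(z) {
    zw <- ag_gather_rows(z, perm)            # (T x C), window-major rows
    zt <- ag_t(zw)                           # (C x T)
    za <- ag_reshape(zt, c(dh, heads, Tw, nW))
    ag_reshape(ag_aperm(za, c(1, 3, 2, 4)), c(dh, Tw, B))
  }
  q <- to_batched(lin_fwd(P, paste0(name, ".q"), h1))
  k <- to_batched(lin_fwd(P, paste0(name, ".k"), h1))
  v <- to_batched(lin_fwd(P, paste0(name, ".v"), h1))
  o <- ag_attention(q, k, v, dh, Tw, B, 1 / sqrt(dh))
  o <- ag_reshape(o, c(dh, Tw, heads, nW))
  o <- ag_reshape(ag_aperm(o, c(1, 3, 2, 4)), c(C, Tw * nW))
  o <- ag_gather_rows(ag_t(o), inv)
  x <- ag_add(x, lin_fwd(P, paste0(name, ".o"), o))
  h2 <- ag_layernorm(x, P[[paste0(name, ".ln2.g")]],
                     P[[paste0(name, ".ln2.be")]])
  ag_add(x, lin_fwd(P, paste0(name, ".m2"),
                    ag_gelu(lin_fwd(P, paste0(name, ".m1"), h2))))
}

merge_perms <- function(g) {
  g2 <- g %/% 2L
  T2 <- prod(g2)
  d2 <- rep(0:(g2[1] - 1), times = g2[2] * g2[3])
  h2 <- rep(rep(0:(g2[2] - 1), each = g2[1]), times = g2[3])
  w2 <- rep(0:(g2[3] - 1), each = g2[1] * g2[2])
  out <- vector("list", 8L)
  j <- 0L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    j <- j + 1L
    out[[j]] <- 1L + (2L * d2 + od) + g[1] * ((2L * h2 + oh) + g[2] * (2L * w2 + ow))
  }
  out
}

stage_ws <- function(g, ws) {
  ws <- min(ws, min(g))
  while (ws > 1L && any(g %% ws != 0L)) ws <- ws - 1L
  as.integer(ws)
}

tokens_to_grid <- function(z, C, g) ag_reshape(ag_t(z), c(C, g))

grid_to_tokens <- function(z, C, g) ag_t(ag_reshape(z, c(C, prod(g))))

encoder_fwd <- function(model, x) {
  cfg <- model$config
  P <- model$P
  F0 <- cfg$base_embed_dim
  dims <- F0 * 2^(0:cfg$n_stages)
  e <- conv_in_relu(P, "stem", x, 2L, 2L)
  g <- dim(ag_value(e))[-1]
  skips <- vector("list", cfg$n_stages)
  z <- grid_to_tokens(e, F0, g)
  for (i in seq_len(cfg$n_stages)) {
    C <- dims[i]
    heads <- max(1L, C %/% 32L)
    ws <- stage_ws(g, cfg$window_size)
    shift <- if (ws > 1L) ws %/% 2L else 0L
    z <- swin_block(P, sprintf("s%d.b1", i), z, g, ws, 0L, heads)
    z <- swin_block(P, sprintf("s%d.b2", i), z, g, ws, shift, heads)
    skips[[i]] <- tokens_to_grid(z, C, g)
    mp <- merge_perms(g)
    zm <- ag_cbind(lapply(mp, function(ix) ag_gather_rows(z, ix)))
    zm <- ag_layernorm(zm, P[[sprintf("s%d.mln.g", i)]],
                       P[[sprintf("s%d.mln.be", i)]])
    z <- lin_fwd(P, sprintf("s%d.merge", i), zm)
    g <- g %/% 2L
  }
  list(bottleneck = tokens_to_grid(z, dims[cfg$n_stages + 1], g),
       skips = skips)
}

res_block <- function(P, name, x) {
  y <- conv_in_relu(P, paste0(name, ".c1"), x, 3L)
  y <- conv_in_relu(P, paste0(name, ".c2"), y, 3L)
  skip <- ag_conv3d(x, P[[paste0(name, ".proj.w")]],
                    P[[paste0(name, ".proj.b")]], 1L)
  ag_relu(ag_add(y, skip))
}

decoder_fwd <- function(model, enc) {
  cfg <- model$config
  P <- model$P
  prev <- enc$bottleneck
  for (i in cfg$n_stages:1) {
    up <- conv_in_relu(P, sprintf("d%d.up", i), ag_upsample2(prev), 3L)
    f <- res_block(P, sprintf("d%d", i),
                   ag_cat_channels(up, enc$skips[[i]]))
    if (cfg$fusion == "drc") {
      f <- ag_add(f, drc_fwd(P, sprintf("d%d.fuse", i), ag_upsample2(prev)))
    } else if (cfg$fusion == "plain_conv") {
      f <- ag_add(f, conv_in_relu(P, sprintf("d%d.fuse", i),
                                  ag_upsample2(prev), 3L))
    }
    prev <- f
  }
  d0 <- conv_in_relu(P, "d0.up", ag_upsample2(prev), 1L)
  ag_sigmoid(ag_conv3d(d0, P[["head.w"]], P[["head.b"]], 1L))
}

#' Forward pass of the segmentation model
#'
#' @param model A `canal_model` from [build_model()].
#' @param patch 3D numeric array (or [intensity_volume()]) whose edges are
#'   divisible by `2^(n_stages + 1)` (32 for the 4-stage model).
#' @param tracked If `TRUE`, return the autograd output node (for training);
#'   otherwise a plain 3D array of probabilities in `(0, 1)`.
#' @return Probability array of the patch shape, or a tracked node.
#' @export
model_forward <- function(model, patch, tracked = FALSE) {
  stopifnot(inherits(model, "canal_model"))
  if (inherits(patch, "intensity_volume")) patch <- patch$voxels
  sh <- dim(patch)
  mult <- required_multiple(model$config)
  if (any(sh %% mult != 0))
    stop(sprintf("patch edges %s must be divisible by %d",
                 paste(sh, collapse = "x"), mult))
  x <- array(patch, c(1L, sh))
  out <- decoder_fwd(model, encoder_fwd(model, x))
  if (tracked) return(out)
  y <- ag_value(out)
  dim(y) <- sh
  y
}

#' Standalone DRC (deep residual convolution) module
#'
#' The two-branch pixel-fusion block: a 1x1x1 convolution branch plus a
#' 1x1x1 / 3x3x3 / 1x1x1 bottleneck branch, each convolution followed by
#' instance normalization and ReLU; the output is their elementwise sum.
#'
#' @param in_channels,out_channels Channel counts.
#' @param seed Seed for the module's parameters.
#' @return A `drc_module` object.
#' @export
drc_module <- function(in_channels, out_channels, seed = 1L) {
  rng <- local_rng(seed)
  r <- mk_registry(rng)
  register_drc(r, "drc", in_channels, out_channels)
  structure(list(P = r$get(), in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "drc_module")
}

#' Forward pass through a DRC module
#'
#' @param mod A [drc_module()].
#' @param x Feature array `(C, D, H, W)` (or tracked node) with
#'   `C = in_channels`.
#' @return Feature array `(out_channels, D, H, W)` (tracked iff `x` is).
#' @export
drc_forward <- function(mod, x) {
  stopifnot(inherits(mod, "drc_module"))
  tracked <- is_ag(x)
  xv <- ag_value(x)
  if (dim(xv)[1] != mod$in_channels)
    stop(sprintf("expected %d input channels, got %d", mod$in_channels,
                 dim(xv)[1]))
  out <- drc_fwd(mod$P, "drc", if (tracked) x else as_ag(xv))
  if (tracked) out else ag_value(out)
}

#' Pixel-level fusion of two decoder levels
#'
#' The coarser level `f_prev` is upsampled x2 (trilinear), passed through
#' the DRC module (whose 1x1x1 branches project the channels to match), and
#' added voxelwise to `f_n`.
#'
#' @param mod A [drc_module()] with `in_channels = channels(f_prev)` and
#'   `out_channels = channels(f_n)`.
#' @param f_n Finer feature array `(C, D, H, W)`.
#' @param f_prev Coarser feature array `(C_prev, D/2, H/2, W/2)`.
#' @return Fused features with the geometry of `f_n`.
#' @export
fuse_features <- function(mod, f_n, f_prev) {
  tracked <- is_ag(f_n) || is_ag(f_prev)
  fn <- as_ag(ag_value(f_n))
  fp <- as_ag(ag_value(f_prev))
  up <- ag_upsample2(fp)
  if (!all(dim(ag_value(up))[-1] == dim(ag_value(fn))[-1]))
    stop("grids incompatible after x2 upsampling")
  out <- ag_add(fn, drc_forward(mod, up))
  if (tracked) out else ag_value(out)
}

# --- checkpoints ------------------------------------------------------------

#' Save a model checkpoint
#'
#' Weights are serialized natively (RDS) with a JSON sidecar recording the
#' model configuration.
#'
#' @param model A `canal_model`.
#' @param path Checkpoint path (e.g. `model.rds`); the sidecar is
#'   `<path>.json`.
#' @export
save_checkpoint <- function(model, path) {
  weights <- lapply(model$P, function(p) p$value)
  saveRDS(list(weights = weights, config = unclass(model$config),
               seed = model$seed), path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path passed to [save_checkpoint()].
#' @return A `canal_model`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  cfg <- structure(x$config, class = "model_config")
  model <- build_model(cfg, seed = x$seed)
  for (nm in names(x$weights)) model$P[[nm]]$value <- x$weights[[nm]]
  model
}

#' Per-stage shape summary
#'
#' @param model A `canal_model`.
#' @param patch Patch edge length (default: 32 for tiny preset, 96 else).
#' @return A data.frame of stage names, grid sizes and channel counts.
#' @export
model_summary <- function(model, patch = NULL) {
  cfg <- model$config
  if (is.null(patch)) patch <- if (cfg$preset == "tiny") 32L else 96L
  F0 <- cfg$base_embed_dim
  g <- patch %/% 2L
  rows <- data.frame(stage = "stem", grid = sprintf("%d^3", g), channels = F0,
                     stringsAsFactors = FALSE)
  for (i in seq_len(cfg$n_stages)) {
    rows <- rbind(rows, data.frame(stage = sprintf("stage%d", i),
                                   grid = sprintf("%d^3", g),
                                   channels = F0 * 2^(i - 1)))
    g <- g %/% 2L
  }
  rows <- rbind(rows, data.frame(stage = "bottleneck", grid = sprintf("%d^3", g),
                                 channels = F0 * 2^cfg$n_stages))
  attr(rows, "n_parameters") <- n_parameters(model)
  rows
}
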