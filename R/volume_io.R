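#' @importFrom RNifti readNifti writeNifti niftiHeader
#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json read_json
NULL

# ---------------------------------------------------------------------------
# Containers. Arrays are indexed (D, H, W) = (axial slice, row, column),
# 0-based in all voxel-coordinate interfaces; spacing is mm per voxel.

new_geometry_checked <- function(voxels, spacing, origin) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  if (any(spacing <= 0)) stop("all spacing components must be > 0")
  list(voxels = voxels, shape = dim(voxels),
       spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Construct an intensity volume
#'
#' A 3D scalar grid with physical geometry. Voxels are expected in `[0, 1]`
#' (use [read_volume()] for min-max rescaling of raw data).
#'
#' @param voxels 3D numeric array, indexed (D, H, W).
#' @param spacing Numeric length-3, mm per voxel along (D, H, W).
#' @param origin Numeric length-3, mm position of voxel (0,0,0).
#' @return An `intensity_volume` object.
#' @export
intensity_volume <- function(voxels, spacing = c(0.3, 0.3, 0.3),
                             origin = c(0, 0, 0)) {
  v <- new_geometry_checked(voxels, spacing, origin)
  n_bad <- sum(!is.finite(v$voxels))
  if (n_bad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s)", n_bad))
  structure(v, class = "intensity_volume")
}

#' Construct a binary mask
#'
#' @inheritParams intensity_volume
#' @param voxels 3D array with values in {0, 1}.
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(voxels, spacing = c(0.3, 0.3, 0.3),
                        origin = c(0, 0, 0)) {
  v <- new_geometry_checked(voxels, spacing, origin)
  u <- unique(as.vector(v$voxels))
  if (!all(u %in% c(0, 1)))
    stop("binary mask values must lie in {0, 1}")
  storage.mode(v$voxels) <- "double"
  structure(v, class = "binary_mask")
}

#' Construct a soft (probability) mask
#'
#' @inheritParams intensity_volume
#' @param voxels 3D array with values in `[0, 1]`.
#' @return A `soft_mask` object.
#' @export
soft_mask <- function(voxels, spacing = c(0.3, 0.3, 0.3), origin = c(0, 0, 0)) {
  v <- new_geometry_checked(voxels, spacing, origin)
  if (any(v$voxels < 0 | v$voxels > 1))
    stop("soft mask values must lie in [0, 1]")
  structure(v, class = "soft_mask")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("<intensity_volume %s, spacing %s mm, range [%.3f, %.3f]>\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, %d foreground voxels (%.3f%%)>\n",
              paste(x$shape, collapse = "x"), sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

#' @export
print.soft_mask <- function(x, ...) {
  cat(sprintf("<soft_mask %s, mean %.4f>\n",
              paste(x$shape, collapse = "x"), mean(x$voxels)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!all(a$shape == b$shape))
    stop(sprintf("shape mismatch: %s vs %s", paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")))
  if (!isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8)))
    stop("spacing mismatch between paired grids")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# NIfTI I/O. On-disk NIfTI axis order is (x, y, z); pixdim carries spacing
# and the sform offset carries the origin. The in-memory (D,H,W) order maps
# directly onto the first three array dimensions.

nifti_geometry <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  # header fields are 32-bit floats; round to their decimal precision
  spacing <- signif(hdr$pixdim[2:4], 6)
  origin <- signif(c(hdr$srow_x[4], hdr$srow_y[4], hdr$srow_z[4]), 6)
  list(spacing = spacing, origin = origin)
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions", length(d)))
  arr <- array(as.numeric(arr), d)
  g <- nifti_geometry(img)
  list(arr = arr, spacing = g$spacing, origin = g$origin)
}

write_nifti_array <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, spacing)
  hdr <- list(srow_x = c(spacing[1], 0, 0, origin[1]),
              srow_y = c(0, spacing[2], 0, origin[2]),
              srow_z = c(0, 0, spacing[3], origin[3]),
              sform_code = 2L)
  img <- RNifti::asNifti(img, reference = hdr)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an intensity volume from NIfTI
#'
#' Loads a 3D `.nii`/`.nii.gz` image. Raw-range intensities (anything
#' outside `[0, 1]`) are min-max rescaled to `[0, 1]`, with constant images
#' mapping to all zeros; data already normalized to `[0, 1]` is read back
#' unchanged, so write/read round trips are lossless at stored precision.
#' Spacing and origin come from the header.
#'
#' @param path Path to a 3D NIfTI file.
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path) {
  x <- read_nifti_array(path)
  n_bad <- sum(!is.finite(x$arr))
  if (n_bad > 0)
    stop(sprintf("volume contains %d non-finite voxel(s): %s", n_bad, path))
  rng <- range(x$arr)
  arr <- if (rng[1] >= 0 && rng[2] <= 1) x$arr
         else if (rng[2] > rng[1]) (x$arr - rng[1]) / (rng[2] - rng[1])
         else array(0, dim(x$arr))
  intensity_volume(arr, x$spacing, x$origin)
}

#' Write an intensity volume to NIfTI
#'
#' Stored as 32-bit float; the `[0, 1]` intensities are written as-is, so a
#' write/read round trip is lossless at single precision.
#'
#' @param vol An [intensity_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  write_nifti_array(vol$voxels, vol$spacing, vol$origin, path, "float")
}

#' Read a binary mask from NIfTI
#'
#' @param path Path to a NIfTI file whose values are {0, 1} (within 1e-6).
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  x <- read_nifti_array(path)
  r <- round(x$arr)
  if (any(abs(x$arr - r) > 1e-6) || any(!r %in% c(0, 1)))
    stop(sprintf("mask file contains values outside {0,1}: %s", path))
  binary_mask(r, x$spacing, x$origin)
}

#' Write a binary mask to NIfTI (unsigned 8-bit)
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  write_nifti_array(mask$voxels, mask$spacing, mask$origin, path, "uint8")
}

# ---------------------------------------------------------------------------
# Run configuration

#' Default run configuration
#'
#' Nested defaults for every pipeline stage. Training defaults mirror the
#' reference protocol (Adam with beta1 = 0.99, initial learning rate 1e-4 with
#' cosine annealing to zero, batch size 1, 500 epochs, 96^3 patches);
#' inference uses a 96^3 sliding window with stride 48; the loss mixes Dice
#' and clDice with lambda = 0.1. The `tiny` model/train preset scales the
#' same architecture down for CPU-sized experiments.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    phantom = list(shape = c(128L, 128L, 128L), spacing = c(0.3, 0.3, 0.3),
                   n_control_points = 4L, radius_range = c(2, 4),
                   contrast_gap = 0.3, noise_sd = 0.05,
                   background_texture = "low", seed = 1L),
    preprocess = list(clip_limit = 2.0, tile_grid = c(8L, 8L),
                      n_bins = 256L, margin_mm = 3.0),
    model = list(preset = "default", in_channels = 1L, base_embed_dim = 48L,
                 n_stages = 4L, window_size = 6L, patch_size = 2L,
                 fusion = "drc", out_channels = 1L, mlp_ratio = 4),
    loss = list(lambda = 0.1, skeleton_iters = 5L, epsilon = 1e-6),
    train = list(lr = 1e-4, beta1 = 0.99, beta2 = 0.999, batch_size = 1L,
                 epochs = 500L, patch = 96L, patches_per_volume = 1L,
                 fg_patch_bias = 0.5, schedule = "cosine", seed = 1L),
    infer = list(window = 96L, stride = 48L, blend = "mean", threshold = 0.5),
    fusion = list(alpha = 0.5, threshold = 0.6, keep_largest_component = TRUE)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop(sprintf("unknown config key: %s", full))
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (cfg$infer$stride > cfg$infer$window) {
    cs_log("warn", "infer.stride %d clamped to window %d",
           cfg$infer$stride, cfg$infer$window)
    cfg$infer$stride <- cfg$infer$window
  }
  lam <- cfg$loss$lambda
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop("loss.lambda must lie in [0, 1]")
  if (cfg$loss$skeleton_iters < 1) stop("loss.skeleton_iters must be >= 1")
  if (!cfg$model$fusion %in% c("none", "plain_conv", "drc"))
    stop("model.fusion must be one of none/plain_conv/drc")
  if (cfg$fusion$alpha < 0 || cfg$fusion$alpha > 1)
    stop("fusion.alpha must lie in [0, 1]")
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Values are merged over [default_config()]; unknown keys are rejected and
#' out-of-range values raise errors.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A validated nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
}

# ---------------------------------------------------------------------------
# Logging

.log_env <- new.env(parent = emptyenv())
.log_env$level <- "info"

#' Set logging verbosity
#' @param level One of "debug", "info", "warn", "quiet".
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "quiet")) {
  .log_env$level <- match.arg(level)
  invisible(.log_env$level)
}

cs_log <- function(level, fmt, ...) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[level]] >= ranks[[.log_env$level]] && .log_env$level != "quiet")
    message(sprintf("[canalseg %s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
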