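# Preprocessing: slice-wise CLAHE contrast enhancement and volume cropping
# to the largest connected canal component (the operational form of
# foramen-guided cropping), plus restoration of cropped predictions to the
# parent geometry.

#' CLAHE parameters
#'
#' @param clip_limit Contrast clip limit (> 0); bounds local noise
#'   amplification.
#' @param tile_grid Integer (gh, gw): contextual tiles per axial slice.
#' @param n_bins Histogram bins.
#' @return A `clahe_params` object.
#' @export
clahe_params <- function(clip_limit = 2.0, tile_grid = c(8L, 8L),
                         n_bins = 256L) {
  stopifnot(clip_limit > 0, length(tile_grid) == 2L, all(tile_grid >= 1L))
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 n_bins = as.integer(n_bins)),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE independently to each axial (D-axis) slice of a volume in
#' `[0, 1]`. Tiles larger than the slice are clamped with a warning.
#'
#' @param vol An [intensity_volume()] with values in `[0, 1]`.
#' @param params A [clahe_params()].
#' @return The enhanced [intensity_volume()], geometry unchanged.
#' @export
clahe_enhance <- function(vol, params = clahe_params()) {
  stopifnot(inherits(vol, "intensity_volume"))
  if (min(vol$voxels) < 0 || max(vol$voxels) > 1)
    stop("clahe_enhance expects intensities in [0, 1]")
  sh <- vol$shape
  tg <- params$tile_grid
  # EBImage requires tile sizes of at least 2 pixels
  max_tiles <- pmax(1L, c(sh[2], sh[3]) %/% 2L)
  if (any(tg > max_tiles)) {
    tg <- pmin(tg, max_tiles)
    cs_log("warn", "tile grid clamped to %dx%d for slice size %dx%d",
           tg[1], tg[2], sh[2], sh[3])
  }
  out <- vol$voxels
  for (s in seq_len(sh[1])) {
    slice <- vol$voxels[s, , ]
    if (max(slice) - min(slice) < 1e-12) next  # flat slice: identity
    eq <- EBImage::clahe(slice, nx = tg[1], ny = tg[2],
                         bins = params$n_bins, limit = params$clip_limit,
                         keep.range = TRUE)
    out[s, , ] <- pmin(pmax(as.numeric(eq), 0), 1)
  }
  intensity_volume(out, vol$spacing, vol$origin)
}

largest_component <- function(mask_voxels) {
  lab <- cs_label26(mask_voxels, dim(mask_voxels))
  if (max(lab) == 0) stop("label mask is empty")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- array(as.numeric(lab == keep), dim(mask_voxels))
  comp
}

#' Locate the canal end openings from a label
#'
#' Restricted to the largest 26-connected component, returns the two
#' component voxels at the extremes of the component's long axis: the voxel
#' farthest from the centroid, and the voxel farthest from it (a standard
#' farthest-point approximation). These correspond to the posterior and
#' anterior canal openings (the mandibular and mental foramina).
#'
#' @param label A nonempty [binary_mask()].
#' @return A 2x3 matrix of 0-based voxel coordinates.
#' @export
locate_foramina <- function(label) {
  stopifnot(inherits(label, "binary_mask"))
  comp <- largest_component(label$voxels)
  idx <- which(comp == 1, arr.ind = TRUE) - 1  # 0-based (d,h,w)
  cen <- colMeans(idx)
  d2 <- rowSums(sweep(idx, 2, cen)^2)
  a <- idx[which.max(d2), ]
  d2a <- rowSums(sweep(idx, 2, a)^2)
  b <- idx[which.max(d2a), ]
  rbind(a, b, deparse.level = 0)
}

#' A crop box
#'
#' Axis-aligned half-open voxel-index box `[lo, hi)` mapping a cropped
#' subvolume back to its parent grid.
#'
#' @param lo,hi Integer length-3, 0-based inclusive start / exclusive end.
#' @param parent_shape Shape of the parent grid.
#' @return A `crop_box` object.
#' @export
crop_box <- function(lo, hi, parent_shape) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  parent_shape <- as.integer(parent_shape)
  if (any(lo < 0) || any(lo >= hi) || any(hi > parent_shape))
    stop("crop box must satisfy 0 <= lo < hi <= parent_shape")
  structure(list(lo = lo, hi = hi, parent_shape = parent_shape),
            class = "crop_box")
}

box_extent <- function(box) box$hi - box$lo

#' Crop a volume/label pair to the canal region
#'
#' The crop box is the bounding box of the label's largest 26-connected
#' component, expanded by `ceil(margin_mm / spacing)` voxels per side and
#' clipped to the grid. Every foreground voxel of the largest component is
#' contained in the crop.
#'
#' @param vol An [intensity_volume()].
#' @param label A nonempty [binary_mask()] aligned with `vol`.
#' @param margin_mm Margin in mm added on every side (default 3).
#' @return A list `(volume, label, box)` with the cropped pair and the
#'   [crop_box()].
#' @export
crop_to_canal <- function(vol, label, margin_mm = 3.0) {
  stopifnot(inherits(vol, "intensity_volume"), inherits(label, "binary_mask"),
            margin_mm >= 0)
  check_aligned(vol, label)
  comp <- largest_component(label$voxels)
  idx <- which(comp == 1, arr.ind = TRUE)  # 1-based
  margin <- ceiling(margin_mm / vol$spacing)
  lo <- pmax(apply(idx, 2, min) - 1 - margin, 0)
  hi <- pmin(apply(idx, 2, max) - 1 + margin + 1, vol$shape)
  box <- crop_box(lo, hi, vol$shape)
  rs <- lapply(1:3, function(j) (box$lo[j] + 1):box$hi[j])
  cropped_vol <- intensity_volume(
    vol$voxels[rs[[1]], rs[[2]], rs[[3]], drop = FALSE],
    vol$spacing, vol$origin + box$lo * vol$spacing)
  cropped_lab <- binary_mask(comp[rs[[1]], rs[[2]], rs[[3]], drop = FALSE],
                             vol$spacing, cropped_vol$origin)
  list(volume = cropped_vol, label = cropped_lab, box = box)
}

#' Restore a cropped mask to the parent geometry
#'
#' Places the cropped content at its box position and fills zeros outside,
#' so `restore_to_original(crop_to_canal(...))` is the identity on the
#' label's largest component.
#'
#' @param cropped A [soft_mask()] or [binary_mask()] with the box extent.
#' @param box The [crop_box()] returned by [crop_to_canal()].
#' @return A mask of the same class at `box$parent_shape`.
#' @export
restore_to_original <- function(cropped, box) {
  stopifnot(inherits(box, "crop_box"))
  if (!all(cropped$shape == box_extent(box)))
    stop(sprintf("cropped shape %s does not match box extent %s",
                 paste(cropped$shape, collapse = "x"),
                 paste(box_extent(box), collapse = "x")))
  out <- array(0, box$parent_shape)
  rs <- lapply(1:3, function(j) (box$lo[j] + 1):box$hi[j])
  out[rs[[1]], rs[[2]], rs[[3]]] <- cropped$voxels
  origin <- cropped$origin - box$lo * cropped$spacing
  if (inherits(cropped, "binary_mask")) binary_mask(out, cropped$spacing, origin)
  else soft_mask(out, cropped$spacing, origin)
}

crop_box_to_json <- function(box, path) {
  jsonlite::write_json(list(lo = box$lo, hi = box$hi,
                            parent_shape = box$parent_shape),
                       path, auto_unbox = FALSE)
  invisible(path)
}

crop_box_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  crop_box(x$lo, x$hi, x$parent_shape)
}
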