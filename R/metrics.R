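# Evaluation metrics for one (prediction, reference) pair: voxel-overlap
# scores (Dice, IoU), the centerline-Dice connectivity score on hard
# skeletons, and surface Hausdorff distances in mm (HD, HD95).

#' Voxelwise confusion counts
#'
#' @param pred,ref Aligned [binary_mask()] objects.
#' @return A list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(pred, ref) {
  stopifnot(inherits(pred, "binary_mask"), inherits(ref, "binary_mask"))
  check_aligned(pred, ref)
  p <- pred$voxels; r <- ref$voxels
  tp <- sum(p * r)
  fp <- sum(p * (1 - r))
  fn <- sum((1 - p) * r)
  list(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (FP + 2 TP + FN)`. Two empty masks give 1 with a logged note.
#'
#' @param c Confusion counts from [confusion_counts()].
#' @return Dice in `[0, 1]`.
#' @export
dice_score <- function(c) {
  if (c$TP + c$FP + c$FN == 0) {
    cs_log("warn", "both masks empty; Dice reported as 1")
    return(1)
  }
  2 * c$TP / (c$FP + 2 * c$TP + c$FN)
}

#' Intersection over union from confusion counts
#'
#' `TP / (TP + FP + FN)`; satisfies `dice = 2 iou / (1 + iou)`.
#'
#' @inheritParams dice_score
#' @return IoU in `[0, 1]`.
#' @export
iou_score <- function(c) {
  if (c$TP + c$FP + c$FN == 0) {
    cs_log("warn", "both masks empty; IoU reported as 1")
    return(1)
  }
  c$TP / (c$TP + c$FP + c$FN)
}

# directed minimum surface-to-surface distances, both directions
surface_dists <- function(pred, ref) {
  A <- cs_surface(pred$voxels, pred$shape)
  B <- cs_surface(ref$voxels, ref$shape)
  list(ab = cs_min_dists(A, B, pred$spacing),
       ba = cs_min_dists(B, A, pred$spacing))
}

hd_from_dists <- function(d, percentile) {
  p <- percentile / 100
  max(stats::quantile(d$ab, p, names = FALSE),
      stats::quantile(d$ba, p, names = FALSE))
}

#' Hausdorff distance between mask surfaces (mm)
#'
#' Surfaces are foreground voxels with a 6-neighbour background (the grid
#' edge counts as background). For percentile `p`, each directed distance is
#' the p-th percentile of the minimum surface-to-surface distances, and the
#' returned value is the maximum of the two directions. `percentile = 100`
#' is the classic Hausdorff distance, 95 gives HD95.
#'
#' @param pred,ref Aligned nonempty [binary_mask()] objects.
#' @param percentile Percentile in (0, 100].
#' @return Distance in mm.
#' @export
hausdorff <- function(pred, ref, percentile = 100) {
  stopifnot(inherits(pred, "binary_mask"), inherits(ref, "binary_mask"))
  check_aligned(pred, ref)
  if (sum(pred$voxels) == 0 || sum(ref$voxels) == 0)
    stop("Hausdorff distance is undefined for an empty mask")
  hd_from_dists(surface_dists(pred, ref), percentile)
}

# Binary skeleton by iterated morphological opening: at each scale the
# residue between the eroded mask and its opening is accumulated. The
# iteration count adapts to the object's maximal thickness.
hard_skeleton <- function(voxels) {
  d <- dim(voxels)
  skel <- array(0, d)
  cur <- voxels
  # pooling ignores out-of-bounds neighbours, so cap at the largest possible
  # inscribed-ball radius to guarantee termination
  for (i in seq_len(ceiling(max(d) / 2) + 1L)) {
    er <- cs_pool3d(cur, d, FALSE)$y
    op <- cs_pool3d(er, d, TRUE)$y
    skel <- pmax(skel, pmin(pmax(cur - op, 0), 1))
    cur <- er
    if (sum(cur) == 0) break
  }
  skel
}

#' Centerline-Dice connectivity score on hard skeletons
#'
#' Topology precision is the fraction of the prediction's skeleton inside
#' the reference volume; topology sensitivity the fraction of the
#' reference's skeleton inside the prediction; the score is their harmonic
#' mean. Skeletons are binary morphological skeletons (iterated
#' erosion-opening residues).
#'
#' @param pred,ref Aligned nonempty [binary_mask()] objects.
#' @return clDice in `[0, 1]`.
#' @export
cldice_score <- function(pred, ref) {
  stopifnot(inherits(pred, "binary_mask"), inherits(ref, "binary_mask"))
  check_aligned(pred, ref)
  if (sum(pred$voxels) == 0 || sum(ref$voxels) == 0)
    stop("clDice is undefined for an empty mask")
  sp <- hard_skeleton(pred$voxels)
  sl <- hard_skeleton(ref$voxels)
  if (sum(sp) == 0 || sum(sl) == 0)
    stop("clDice is undefined for an empty skeleton")
  tprec <- sum(sp * ref$voxels) / sum(sp)
  tsens <- sum(sl * pred$voxels) / sum(sl)
  if (tprec + tsens == 0) return(0)
  2 * tprec * tsens / (tprec + tsens)
}

#' Evaluate a soft prediction against a reference mask
#'
#' Binarizes the prediction at `threshold` and computes Dice, IoU, clDice
#' and surface distances. If either binary mask is empty the overlap scores
#' are still reported (0, or 1 when both are empty) and the distance and
#' clDice fields are `NA` (flagged `undefined_distances`).
#'
#' @param pred A [soft_mask()] or [binary_mask()].
#' @param ref A [binary_mask()] aligned with `pred`.
#' @param threshold Binarization threshold (default 0.5).
#' @return A `metrics_report` list: `dice`, `iou`, `cldice`, `hd_mm`,
#'   `hd95_mm`, `counts`, `undefined_distances`, `skeleton`.
#' @export
evaluate <- function(pred, ref, threshold = 0.5) {
  stopifnot(inherits(ref, "binary_mask"))
  check_aligned(pred, ref)
  pb <- binary_mask(array(as.numeric(pred$voxels >= threshold), pred$shape),
                    pred$spacing, pred$origin)
  counts <- confusion_counts(pb, ref)
  undef <- sum(pb$voxels) == 0 || sum(ref$voxels) == 0
  d <- if (undef) NULL else surface_dists(pb, ref)
  rep <- list(dice = dice_score(counts), iou = iou_score(counts),
              cldice = if (undef) NA_real_ else cldice_score(pb, ref),
              hd_mm = if (undef) NA_real_ else hd_from_dists(d, 100),
              hd95_mm = if (undef) NA_real_ else hd_from_dists(d, 95),
              counts = counts, undefined_distances = undef,
              skeleton = "morphological")
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f | IoU %.4f | clDice %s | HD %s mm | HD95 %s mm\n",
              x$dice, x$iou,
              ifelse(is.na(x$cldice), "NA", sprintf("%.4f", x$cldice)),
              ifelse(is.na(x$hd_mm), "NA", sprintf("%.3f", x$hd_mm)),
              ifelse(is.na(x$hd95_mm), "NA", sprintf("%.3f", x$hd95_mm))))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` from [evaluate()].
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
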