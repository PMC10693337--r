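# Synthetic canal phantoms: a low-contrast curved tube inside a bone-like
# textured volume, with dense, sparse-slice and circular-expansion labels.
# These reproduce the statistical regime of clinical canal data (foreground
# below 2% of voxels, small intensity gap to background) without any
# anatomical modelling.

#' Specify a canal phantom
#'
#' @param shape Integer length-3 grid size (D, H, W).
#' @param spacing mm per voxel.
#' @param endpoints 2x3 matrix of 0-based voxel coordinates: the synthetic
#'   posterior (mandibular-foramen) and anterior (mental-foramen) canal ends.
#'   Default: a diagonal pair well inside the grid.
#' @param n_control_points Number of spline control points (>= 2) for the
#'   centerline; 2 gives a straight canal.
#' @param radius_range `(r_min, r_max)` tube radius in voxels; `r_min >= 1`.
#' @param contrast_gap Mean intensity difference between bone background
#'   (0.6) and the canal, in `(0, 1]`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param background_texture "low" or "high" spatial-frequency bone texture.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 128L),
                         spacing = c(0.3, 0.3, 0.3),
                         endpoints = NULL,
                         n_control_points = 4L,
                         radius_range = c(2, 4),
                         contrast_gap = 0.3,
                         noise_sd = 0.05,
                         background_texture = c("low", "high"),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(endpoints)) {
    m <- pmax(4, round(0.15 * shape))
    endpoints <- rbind(m, shape - 1L - m)
  }
  endpoints <- matrix(as.numeric(endpoints), 2, 3)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            n_control_points >= 2L, length(radius_range) == 2L)
  if (radius_range[1] < 1) stop("r_min must be >= 1 voxel")
  if (radius_range[2] < radius_range[1]) stop("radius_range must be ordered")
  if (contrast_gap <= 0 || contrast_gap > 1)
    stop("contrast_gap must lie in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(endpoints < 0) || any(sweep(endpoints, 2, shape - 1) > 0))
    stop("endpoints must lie inside the grid")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 endpoints = endpoints,
                 n_control_points = as.integer(n_control_points),
                 radius_range = as.numeric(radius_range),
                 contrast_gap = contrast_gap, noise_sd = noise_sd,
                 background_texture = match.arg(background_texture),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Sample a smooth canal centerline
#'
#' Interpolating cubic splines (one per coordinate, natural boundary) pass
#' through the two endpoints and `n_control_points - 2` seeded random
#' interior control points, sampled at arc steps of at most 0.5 voxels.
#'
#' @param spec A [phantom_spec()].
#' @return An `n x 3` matrix of ordered real-valued voxel coordinates.
#' @export
make_centerline <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$endpoints[1, ]
  b <- spec$endpoints[2, ]
  if (sqrt(sum((a - b)^2)) < 4 * spec$radius_range[2])
    stop("endpoints closer than 4 * r_max; tube would self-overlap")
  k <- spec$n_control_points
  ctrl <- matrix(0, k, 3)
  ctrl[1, ] <- a
  ctrl[k, ] <- b
  if (k > 2) {
    rng <- local_rng(spec$seed + 101L)
    for (i in 2:(k - 1)) {
      t <- (i - 1) / (k - 1)
      base <- (1 - t) * a + t * b
      # lateral jitter scaled to the grid but kept away from the faces
      jit <- rng$runif(3, -0.12, 0.12) * spec$shape
      p <- base + jit
      lo <- spec$radius_range[2] + 1
      ctrl[i, ] <- pmin(pmax(p, lo), spec$shape - 1 - lo)
    }
  }
  # chord-length parameterisation, then dense spline sampling
  seg <- sqrt(rowSums((ctrl[-1, , drop = FALSE] -
                         ctrl[-k, , drop = FALSE])^2))
  tpar <- c(0, cumsum(seg))
  n_dense <- max(64L, ceiling(4 * sum(seg)))
  tt <- seq(0, tpar[k], length.out = n_dense)
  dense <- sapply(1:3, function(j) {
    if (k == 2) approx(tpar, ctrl[, j], xout = tt)$y
    else stats::spline(tpar, ctrl[, j], xout = tt, method = "natural")$y
  })
  # resample to <= 0.5-voxel arc steps
  dl <- sqrt(rowSums((dense[-1, , drop = FALSE] -
                        dense[-nrow(dense), , drop = FALSE])^2))
  s <- c(0, cumsum(dl))
  n_out <- max(2L, ceiling(s[length(s)] / 0.5) + 1L)
  so <- seq(0, s[length(s)], length.out = n_out)
  pts <- sapply(1:3, function(j) approx(s, dense[, j], xout = so)$y)
  if (any(pts < 0) || any(sweep(pts, 2, spec$shape - 1) > 0))
    stop("centerline leaves the grid; reduce jitter or enlarge the grid")
  pts
}

#' Rasterize a tube around a centerline
#'
#' The mask is the union of balls centred on the centerline points with the
#' given per-point radii (clamped below at 1 voxel).
#'
#' @param centerline `n x 3` matrix of 0-based voxel coordinates.
#' @param radius_profile Radius in voxels per centerline point (recycled).
#' @param shape Grid size (D, H, W).
#' @param spacing mm per voxel.
#' @return A [binary_mask()] forming a single 26-connected component.
#' @export
rasterize_tube <- function(centerline, radius_profile, shape,
                           spacing = c(0.3, 0.3, 0.3)) {
  centerline <- matrix(centerline, ncol = 3)
  radii <- pmax(1, rep_len(radius_profile, nrow(centerline)))
  out_lo <- sweep(centerline - radii, 2, c(0, 0, 0), `<`)
  out_hi <- sweep(centerline + radii, 2, shape - 1, `>`)
  bad <- which(rowSums(out_lo | out_hi) > 0)
  if (length(bad))
    stop(sprintf("tube exits the grid at centerline point %d (%.1f, %.1f, %.1f)",
                 bad[1], centerline[bad[1], 1], centerline[bad[1], 2],
                 centerline[bad[1], 3]))
  vox <- cs_rasterize_tube(centerline, radii, as.integer(shape))
  binary_mask(vox, spacing)
}

# Seeded RNG scoped to a closure so phantom generation never disturbs the
# caller's RNG stream.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  withstate <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    f(...)
  }
  list(runif = withstate(stats::runif), rnorm = withstate(stats::rnorm),
       sample = withstate(base::sample))
}

#' Generate a canal phantom
#'
#' Background is seeded band-limited noise around mean 0.6 (bone-like
#' texture); canal voxels sit `contrast_gap` below it; optional additive
#' Gaussian noise; intensities clipped to `[0, 1]`.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` ([intensity_volume()]), `label`
#'   ([binary_mask()]), and `endpoints` (the spec's 2x3 endpoint matrix).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cl <- make_centerline(spec)
  rng <- local_rng(spec$seed + 202L)
  n <- nrow(cl)
  # smooth radius profile within the allowed range
  r0 <- rng$runif(1, spec$radius_range[1], spec$radius_range[2])
  ph <- rng$runif(1, 0, 2 * pi)
  radii <- r0 + 0.5 * (spec$radius_range[2] - spec$radius_range[1]) *
    sin(seq(0, 2 * pi, length.out = n) + ph)
  radii <- pmin(pmax(radii, spec$radius_range[1]), spec$radius_range[2])
  label <- rasterize_tube(cl, radii, spec$shape, spec$spacing)

  texture_sd <- if (spec$background_texture == "low") 0.05 else 0.1
  blur_passes <- if (spec$background_texture == "low") 2L else 1L
  raw <- array(rng$rnorm(prod(spec$shape)), spec$shape)
  tex <- cs_boxblur3d(raw, as.integer(spec$shape), 2L, blur_passes)
  tex <- tex / stats::sd(tex) * texture_sd
  vox <- 0.6 + tex
  vox[label$voxels == 1] <- 0.6 - spec$contrast_gap
  if (spec$noise_sd > 0)
    vox <- vox + array(rng$rnorm(prod(spec$shape), sd = spec$noise_sd),
                       spec$shape)
  vox <- pmin(pmax(vox, 0), 1)
  list(volume = intensity_volume(vox, spec$spacing),
       label = label, endpoints = spec$endpoints)
}

# ---------------------------------------------------------------------------
# Sparse annotations and circular expansion

#' Construct a sparse annotation
#'
#' A set of annotated axial 2D slices standing in for per-slice expert
#' labels of a 3D volume.
#'
#' @param entries List of `list(slice = index0, mask = 2D {0,1} matrix)`,
#'   with strictly increasing 0-based slice indices along the D axis.
#' @param parent_shape Shape (D, H, W) of the parent volume.
#' @param spacing mm per voxel.
#' @return A `sparse_annotation` object.
#' @export
sparse_annotation <- function(entries, parent_shape, spacing = c(0.3, 0.3, 0.3)) {
  idx <- vapply(entries, function(e) e$slice, numeric(1))
  if (length(idx) && (any(diff(idx) <= 0) || any(idx < 0) ||
                      any(idx >= parent_shape[1])))
    stop("slice indices must be strictly increasing and inside the grid")
  for (e in entries) {
    if (!all(dim(e$mask) == parent_shape[2:3]))
      stop("each 2D mask must match the parent (H, W)")
    if (sum(e$mask) == 0) stop("annotated slices must be nonempty")
  }
  structure(list(entries = entries, parent_shape = as.integer(parent_shape),
                 spacing = as.numeric(spacing)),
            class = "sparse_annotation")
}

#' Sample a sparse slice annotation from a dense mask
#'
#' Slice indices are drawn without replacement (seeded) from the nonempty
#' axial slices; each entry is the exact 2D restriction of the mask.
#'
#' @param mask A [binary_mask()].
#' @param n_slices Number of slices to annotate.
#' @param seed Integer seed for the slice draw.
#' @return A [sparse_annotation()].
#' @export
make_sparse_annotation <- function(mask, n_slices, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  per_slice <- apply(mask$voxels, 1, sum)
  nonempty <- which(per_slice > 0)
  if (length(nonempty) == 0) stop("mask is empty; nothing to annotate")
  if (n_slices > length(nonempty))
    stop(sprintf("n_slices (%d) exceeds the %d nonempty slices", n_slices,
                 length(nonempty)))
  rng <- local_rng(seed)
  chosen <- sort(rng$sample(nonempty, n_slices))
  entries <- lapply(chosen, function(s)
    list(slice = s - 1L, mask = mask$voxels[s, , ]))
  sparse_annotation(entries, mask$shape, mask$spacing)
}

#' Expand sparse slice annotations into a circular-expansion mask
#'
#' Per annotated slice the centroid and equivalent radius (radius of the
#' circle with the slice mask's area) are fitted; centroid and radius are
#' linearly interpolated between consecutive annotated slices and a disk is
#' rasterized on every intermediate slice. This mirrors how approximate
#' dense labels are built from per-slice canal annotations.
#'
#' @param sparse A [sparse_annotation()] with at least two entries.
#' @param parent_shape Shape of the output mask (defaults to the
#'   annotation's parent shape).
#' @return A [binary_mask()].
#' @export
make_circular_expansion <- function(sparse, parent_shape = NULL) {
  stopifnot(inherits(sparse, "sparse_annotation"))
  if (length(sparse$entries) < 2)
    stop("circular expansion needs at least 2 annotated slices")
  if (is.null(parent_shape)) parent_shape <- sparse$parent_shape
  slices <- vapply(sparse$entries, function(e) e$slice, numeric(1))
  cents <- t(vapply(sparse$entries, function(e) {
    w <- which(e$mask == 1, arr.ind = TRUE)
    colMeans(w) - 1  # 0-based
  }, numeric(2)))
  radii <- vapply(sparse$entries, function(e) sqrt(sum(e$mask) / pi),
                  numeric(1))
  out <- array(0, parent_shape)
  H <- parent_shape[2]; W <- parent_shape[3]
  hh <- matrix(rep(0:(H - 1), W), H, W)
  ww <- matrix(rep(0:(W - 1), each = H), H, W)
  for (i in seq_len(length(slices) - 1)) {
    s0 <- slices[i]; s1 <- slices[i + 1]
    for (s in s0:s1) {
      t <- if (s1 > s0) (s - s0) / (s1 - s0) else 0
      ce <- (1 - t) * cents[i, ] + t * cents[i + 1, ]
      r <- (1 - t) * radii[i] + t * radii[i + 1]
      disk <- (hh - ce[1])^2 + (ww - ce[2])^2 <= r^2
      out[s + 1, , ] <- pmax(out[s + 1, , ], disk)
    }
  }
  binary_mask(out, sparse$spacing)
}

#' Stack a sparse annotation into a (partial) dense mask
#'
#' Annotated slices are placed at their indices; all other slices are zero.
#'
#' @param sparse A [sparse_annotation()].
#' @return A [binary_mask()].
#' @export
sparse_to_mask <- function(sparse) {
  out <- array(0, sparse$parent_shape)
  for (e in sparse$entries) out[e$slice + 1, , ] <- e$mask
  binary_mask(out, sparse$spacing)
}
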