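# Shared fixtures: small phantoms and hand-built masks, generated in code.

make_test_phantom <- function(seed, shape = c(32L, 32L, 32L),
                              contrast_gap = 0.4, noise_sd = 0.05,
                              radius_range = c(2, 3.5),
                              n_control_points = 3L) {
  spec <- phantom_spec(shape = shape, n_control_points = n_control_points,
                       radius_range = radius_range,
                       contrast_gap = contrast_gap, noise_sd = noise_sd,
                       seed = seed)
  generate_phantom(spec)
}

make_test_pairs <- function(seeds, ...) {
  lapply(seeds, function(s) {
    ph <- make_test_phantom(s, ...)
    list(volume = ph$volume, label = ph$label)
  })
}

# straight tube along the D axis, radius r, spanning slices d0..d1 (1-based)
straight_tube <- function(shape, d0, d1, centre_hw, r) {
  arr <- array(0, shape)
  for (d in d0:d1)
    for (h in 1:shape[2])
      for (w in 1:shape[3])
        if ((h - centre_hw[1])^2 + (w - centre_hw[2])^2 <= r^2)
          arr[d, h, w] <- 1
  arr
}

# 10-voxel 1-wide line and its 5-voxel prediction, used by the worked
# centerline-Dice example
line_pair <- function() {
  ref <- array(0, c(14, 5, 5))
  ref[3:12, 3, 3] <- 1
  pred <- array(0, c(14, 5, 5))
  pred[3:7, 3, 3] <- 1
  list(ref = ref, pred = pred)
}

random_mask_pair <- function(shape, p = 0.4, nonempty = FALSE) {
  repeat {
    a <- array(as.numeric(stats::runif(prod(shape)) < p), shape)
    b <- array(as.numeric(stats::runif(prod(shape)) < p), shape)
    if (!nonempty || (sum(a) > 0 && sum(b) > 0))
      return(list(a = a, b = b))
  }
}

# vectorized surface + all-pairs Hausdorff oracle (independent of the
# package's compiled implementation): surfaces via shifted-array neighbour
# tests, distances via the expanded squared-norm identity
hd_oracle_fast <- function(a, b, spacing, percentile) {
  surf <- function(m) {
    sh <- dim(m)
    pad <- array(0, sh + 2)
    pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- m
    ctr <- pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)]
    nbmin <- pmin(pad[1:sh[1], 2:(sh[2] + 1), 2:(sh[3] + 1)],
                  pad[3:(sh[1] + 2), 2:(sh[2] + 1), 2:(sh[3] + 1)],
                  pad[2:(sh[1] + 1), 1:sh[2], 2:(sh[3] + 1)],
                  pad[2:(sh[1] + 1), 3:(sh[2] + 2), 2:(sh[3] + 1)],
                  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 1:sh[3]],
                  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 3:(sh[3] + 2)])
    which(ctr == 1 & nbmin == 0, arr.ind = TRUE) - 1
  }
  A <- sweep(surf(a), 2, spacing, `*`)
  B <- sweep(surf(b), 2, spacing, `*`)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  p <- percentile / 100
  max(quantile(apply(d, 1, min), p, names = FALSE),
      quantile(apply(d, 2, min), p, names = FALSE))
}
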