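#' @useDynLib canalseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal reverse-mode automatic differentiation over R arrays.
#
# A node is an environment holding `value` (numeric array/scalar), its
# `parents` (list of nodes), and `backfn(node, grad)` returning one gradient
# per parent. `ag_backward()` topologically sorts the tape and accumulates
# gradients into every node; trainable parameters read `$grad` afterwards.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L
.ag$stamp <- 0L

ag_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  .ag$counter <- .ag$counter + 1L
  n$id <- .ag$counter
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$grad <- NULL
  class(n) <- "ag_node"
  n
}

is_ag <- function(x) inherits(x, "ag_node")

as_ag <- function(x) if (is_ag(x)) x else ag_node(x)

ag_value <- function(x) if (is_ag(x)) x$value else x

#' @export
print.ag_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag_node", if (is.null(d)) paste0("len ", length(x$value)) else
    paste(d, collapse = "x"), ">\n")
  invisible(x)
}

# Topological order by depth-first search, then reverse sweep.
ag_backward <- function(out, grad = NULL) {
  if (is.null(grad)) {
    stopifnot(length(out$value) == 1L)
    grad <- 1
  }
  order <- vector("list", 2048L)
  n_ord <- 0L
  .ag$stamp <- .ag$stamp + 1L
  stamp <- .ag$stamp
  stack <- list(list(node = out, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (top$stage == 1L) {
      if (identical(node$seen, stamp)) next
      node$seen <- stamp
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (!identical(p$seen, stamp))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  for (i in seq_len(n_ord)) order[[i]]$grad <- NULL
  out$grad <- grad
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node, node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

# --- elementwise and linear-algebra primitives ------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value + b$value, list(a, b), function(node, g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value - b$value, list(a, b), function(node, g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value * b$value, list(a, b),
          function(node, g) list(g * b$value, g * a$value))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value / b$value, list(a, b), function(node, g)
    list(g / b$value, -g * a$value / (b$value^2)))
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_node(a$value * s, list(a), function(node, g) list(g * s))
}

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value %*% b$value, list(a, b), function(node, g) {
    list(g %*% t(b$value), crossprod(a$value, g))
  })
}

ag_addvec_rows <- function(a, v) {
  # add a length-ncol vector to every row of a matrix
  a <- as_ag(a); v <- as_ag(v)
  nr <- nrow(a$value)
  ag_node(a$value + rep(v$value, each = nr), list(a, v),
          function(node, g) list(g, colSums(g)))
}

ag_relu <- function(a) {
  a <- as_ag(a)
  m <- a$value > 0
  ag_node(a$value * m, list(a), function(node, g) list(g * m))
}

ag_gelu <- function(a) {
  # sigmoid-weighted form of the Gaussian-error linear unit
  a <- as_ag(a)
  x <- a$value
  s <- 1 / (1 + exp(-1.702 * x))
  ag_node(x * s, list(a),
          function(node, g) list(g * (s + 1.702 * x * s * (1 - s))))
}

ag_log <- function(a) {
  a <- as_ag(a)
  ag_node(log(a$value), list(a), function(node, g) list(g / a$value))
}

ag_sigmoid <- function(a) {
  a <- as_ag(a)
  y <- 1 / (1 + exp(-a$value))
  ag_node(y, list(a), function(node, g) list(g * y * (1 - y)))
}

ag_sum <- function(a) {
  a <- as_ag(a)
  shp <- dim(a$value)
  len <- length(a$value)
  ag_node(sum(a$value), list(a), function(node, g) {
    gx <- rep(g, len)
    if (!is.null(shp)) dim(gx) <- shp
    list(gx)
  })
}

ag_reshape <- function(a, newdim) {
  a <- as_ag(a)
  olddim <- dim(a$value)
  v <- a$value
  dim(v) <- newdim
  ag_node(v, list(a), function(node, g) {
    dim(g) <- olddim
    list(g)
  })
}

ag_t <- function(a) {
  a <- as_ag(a)
  ag_node(t(a$value), list(a), function(node, g) list(t(g)))
}

ag_aperm <- function(a, perm) {
  a <- as_ag(a)
  inv <- order(perm)
  ag_node(aperm(a$value, perm), list(a),
          function(node, g) list(aperm(g, inv)))
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  ag_node(do.call(cbind, vals), nodes, function(node, g) {
    lapply(seq_along(ncols), function(j)
      g[, starts[j]:ends[j], drop = FALSE])
  })
}

# Row gather by index; backward scatters through the inverse permutation.
ag_gather_rows <- function(a, idx) {
  a <- as_ag(a)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(node, g) {
    gx <- matrix(0, nrow(a$value), ncol(a$value))
    gx[idx, ] <- g
    list(gx)
  })
}

ag_cat_rows <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  na <- nrow(a$value)
  ag_node(rbind(a$value, b$value), list(a, b), function(node, g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

ag_cat_channels <- function(a, b) {
  # (Ca,D,H,W) and (Cb,D,H,W) -> (Ca+Cb,D,H,W)
  a <- as_ag(a); b <- as_ag(b)
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(all(da[-1] == db[-1]))
  ca <- da[1]
  out <- array(0, c(ca + db[1], da[-1]))
  out[seq_len(ca), , , ] <- a$value
  out[ca + seq_len(db[1]), , , ] <- b$value
  ag_node(out, list(a, b), function(node, g) {
    list(array(g[seq_len(ca), , , ], da),
         array(g[ca + seq_len(db[1]), , , ], db))
  })
}

# Layer normalisation over the columns of each row of a (T x C) matrix.
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ag(a); gamma <- as_ag(gamma); beta <- as_ag(beta)
  x <- a$value
  C <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  nr <- nrow(x)
  y <- xhat * rep(gamma$value, each = nr) + rep(beta$value, each = nr)
  ag_node(y, list(a, gamma, beta), function(node, g) {
    gg <- colSums(g * xhat)
    gb <- colSums(g)
    gxhat <- g * rep(gamma$value, each = nr)
    gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(gx, gg, gb)
  })
}

# Instance normalisation of (C,D,H,W): each channel normalised over space.
# With a single spatial sample the statistics are degenerate (they would
# zero the signal), so the op reduces to the learnable affine map.
ag_instancenorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ag(a); gamma <- as_ag(gamma); beta <- as_ag(beta)
  x <- a$value
  d <- dim(x)
  C <- d[1]; n <- prod(d[-1])
  if (n == 1L) {
    y <- x * gamma$value + beta$value
    dim(y) <- d
    return(ag_node(y, list(a, gamma, beta), function(node, g) {
      gm <- as.numeric(g)
      gx <- gm * gamma$value
      dim(gx) <- d
      list(gx, gm * as.numeric(x), gm)
    }))
  }
  xm <- matrix(x, C, n)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- xhat * gamma$value + beta$value
  dim(y) <- d
  ag_node(y, list(a, gamma, beta), function(node, g) {
    gm <- matrix(g, C, n)
    gg <- rowSums(gm * xhat)
    gb <- rowSums(gm)
    gxhat <- gm * gamma$value
    gx <- inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    dim(gx) <- d
    list(gx, gg, gb)
  })
}

# --- compiled-kernel ops ----------------------------------------------------

ag_conv3d <- function(x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  x <- as_ag(x); w <- as_ag(w); b <- as_ag(b)
  xdim <- dim(x$value)
  cout <- nrow(w$value)
  if (k == 1L && stride == 1L) {
    # pointwise convolution: a channel-mixing matrix product, no im2col
    n <- prod(xdim[-1])
    xm <- x$value
    dim(xm) <- c(xdim[1], n)
    y <- w$value %*% xm + b$value
    dim(y) <- c(cout, xdim[-1])
    return(ag_node(y, list(x, w, b), function(node, g) {
      dim(g) <- c(cout, n)
      gx <- crossprod(w$value, g)
      dim(gx) <- xdim
      list(gx, tcrossprod(g, xm), rowSums(g))
    }))
  }
  odim <- c(cout, (xdim[-1] + 2L * pad - k) %/% stride + 1L)
  cols <- cs_im2col(x$value, xdim, k, stride, pad)
  y <- w$value %*% cols + b$value
  dim(y) <- odim
  ag_node(y, list(x, w, b), function(node, g) {
    dim(g) <- c(cout, prod(odim[-1]))
    gx <- cs_col2im(crossprod(w$value, g), xdim, k, stride, pad)
    gw <- tcrossprod(g, cols)
    cols <<- NULL  # release the buffer; backward runs once per node
    list(gx, gw, rowSums(g))
  })
}

ag_pool3d <- function(x, take_max = TRUE) {
  x <- as_ag(x)
  d <- dim(x$value)
  fw <- cs_pool3d(x$value, d, take_max)
  ag_node(fw$y, list(x), function(node, g)
    list(cs_pool3d_bwd(g, fw$arg, d)))
}

ag_upsample2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  ag_node(cs_upsample2_fwd(x$value, d), list(x),
          function(node, g) list(cs_upsample2_bwd(g, d)))
}

ag_attention <- function(q, k, v, dh, Tn, B, scale) {
  q <- as_ag(q); k <- as_ag(k); v <- as_ag(v)
  fw <- cs_attn_fwd(q$value, k$value, v$value, dh, Tn, B, scale)
  ag_node(fw$o, list(q, k, v), function(node, g) {
    bw <- cs_attn_bwd(g, q$value, k$value, v$value, fw$p, dh, Tn, B, scale)
    list(bw$gq, bw$gk, bw$gv)
  })
}

# Fused instance normalisation + ReLU over (C, D, H, W), compiled.
ag_innorm_relu <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_ag(a); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(a$value)
  fw <- cs_innr_fwd(a$value, d, gamma$value, beta$value, eps)
  ag_node(fw$y, list(a, gamma, beta), function(node, g) {
    bw <- cs_innr_bwd(g, fw$y, fw$xhat, fw$inv, gamma$value, d)
    list(bw$gx, bw$gg, bw$gb)
  })
}
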