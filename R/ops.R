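## Differentiable array operations. Convolutions go through im2col + BLAS
## GEMM; pooling/resampling adjoints are exact (same C++ kernels in both
## directions), which the finite-difference tests rely on.

dims4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a 4-d array", call. = FALSE)
  d
}

same_pad <- function(k) {
  if (k %% 2L == 0L) {
    stop("even kernel size ", k, " has no same-padding; use an odd size",
         call. = FALSE)
  }
  (k - 1L) %/% 2L
}

## 2-D convolution. Weight is stored as a (kh*kw*Cin) x Cout matrix whose
## rows are ordered (dh, dw, cin) to match k_im2col's column order.
op_conv2d <- function(x, w, b, kh, kw, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- same_pad(kh)
  d <- dims4(x$value)
  cin <- nrow(w$value) / (kh * kw)
  if (cin != d[4]) {
    stop(sprintf("conv2d: weight expects %d input channels, got %d",
                 cin, d[4]), call. = FALSE)
  }
  one <- kh == 1L && kw == 1L && stride == 1L && pad == 0L
  if (one) {
    ## 1x1 fast path: im2col is a pure reshape in this layout
    M <- x$value
    dim(M) <- c(d[1] * d[2] * d[3], d[4])
  } else {
    M <- k_im2col(x$value, d, kh, kw, as.integer(stride), as.integer(pad))
  }
  out <- M %*% w$value
  cout <- ncol(out)
  k_add_bias(out, b$value)  # in place; `out` is freshly allocated
  oh <- (d[1] + 2L * pad - kh) %/% stride + 1L
  ow <- (d[2] + 2L * pad - kw) %/% stride + 1L
  dim(out) <- c(oh, ow, d[3], cout)
  ag_op(out, list(x, w, b), function() {
    force(M); force(d)
    function(g) {
      G <- g
      dim(G) <- c(length(g) / cout, cout)
      gw <- crossprod(M, G)
      gb <- colSums(G)
      gx <- tcrossprod(G, w$value)
      if (one) {
        dim(gx) <- d
      } else {
        gx <- k_col2im(gx, d, kh, kw, as.integer(stride), as.integer(pad))
      }
      M <<- NULL
      list(gx, gw, gb)
    }
  })
}

## Transposed convolution (stride-2 4x4 by default). Weight is the kernel of
## the adjoint convolution: a (k*k*Cout) x Cin matrix, so the forward pass is
## col2im and the backward pass is a plain convolution.
op_conv_transpose2d <- function(x, w, b, k = 4L, stride = 2L, pad = 1L) {
  d <- dims4(x$value)
  X <- x$value
  dim(X) <- c(d[1] * d[2] * d[3], d[4])
  cols <- tcrossprod(X, w$value)
  cout <- nrow(w$value) / (k * k)
  oh <- (d[1] - 1L) * stride - 2L * pad + k
  ow <- (d[2] - 1L) * stride - 2L * pad + k
  odims <- c(oh, ow, d[3], as.integer(cout))
  out <- k_col2im(cols, as.integer(odims), k, k,
                  as.integer(stride), as.integer(pad))
  k_add_bias(out, b$value)
  dim(out) <- odims
  ag_op(out, list(x, w, b), function() {
    force(X)
    function(g) {
      M <- k_im2col(g, as.integer(odims), k, k,
                    as.integer(stride), as.integer(pad))
      gx <- M %*% w$value
      dim(gx) <- d
      gw <- crossprod(M, X)
      gm <- g
      dim(gm) <- c(oh * ow * d[3], cout)
      gb <- colSums(gm)
      X <<- NULL
      list(gx, gw, gb)
    }
  })
}

## Batch normalization over (H, W, N) per channel. `layer` is an environment
## holding running_mean / running_var, updated as a side effect in training.
op_batchnorm <- function(x, gamma, beta, layer, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- dims4(x$value)
  m <- d[1] * d[2] * d[3]
  C <- d[4]
  if (training) {
    st <- k_bn_stats(x$value, C)
    mu <- st$mu
    v <- st$var
    if (m > 1) {
      layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
      layer$running_var <- (1 - momentum) * layer$running_var +
        momentum * v * m / (m - 1)
    }
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv <- 1 / sqrt(v + eps)
  out <- k_bn_apply(x$value, mu, inv, gamma$value, beta$value)
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function() {
    function(g) {
      r <- k_bn_bwd(x$value, g, mu, inv, gamma$value, training)
      gx <- r$gx
      dim(gx) <- d
      list(gx, r$dgamma, r$dbeta)
    }
  })
}

op_relu <- function(x) {
  v <- k_relu(x$value)
  dim(v) <- dim(x$value)
  ag_op(v, list(x), function() {
    force(v)
    function(g) list(k_relu_bwd(g, v))
  })
}

op_sigmoid <- function(x) {
  y <- k_sigmoid(x$value)
  dim(y) <- dim(x$value)
  ag_op(y, list(x), function() {
    force(y)
    function(g) list(k_sigmoid_bwd(g, y))
  })
}

op_add <- function(a, b) {
  ag_op(a$value + b$value, list(a, b), function() {
    function(g) list(g, g)
  })
}

## Sum of n same-shaped nodes (CGR path aggregation).
op_add_n <- function(nodes) {
  v <- nodes[[1]]$value
  for (i in seq_along(nodes)[-1]) v <- v + nodes[[i]]$value
  ag_op(v, nodes, function() {
    function(g) rep(list(g), length(nodes))
  })
}

op_mul <- function(a, b) {
  ag_op(a$value * b$value, list(a, b), function() {
    function(g) list(g * b$value, g * a$value)
  })
}

## Concatenate along the channel (last) axis; contiguous in this layout.
op_concat_c <- function(nodes) {
  ds <- lapply(nodes, function(n) dims4(n$value))
  base <- ds[[1]][1:3]
  for (d in ds) stopifnot(identical(d[1:3], base))
  cs <- vapply(ds, function(d) d[4], integer(1))
  v <- unlist(lapply(nodes, function(n) as.vector(n$value)), use.names = FALSE)
  dim(v) <- c(base, sum(cs))
  ag_op(v, nodes, function() {
    function(g) {
      plane <- prod(base)
      off <- 0L
      out <- vector("list", length(nodes))
      for (i in seq_along(nodes)) {
        gi <- g[seq.int(off + 1L, off + plane * cs[i])]
        dim(gi) <- c(base, cs[i])
        out[[i]] <- gi
        off <- off + plane * cs[i]
      }
      out
    }
  })
}

op_maxpool <- function(x, k, stride = k, pad = 0L) {
  d <- dims4(x$value)
  r <- k_maxpool(x$value, d, as.integer(k), as.integer(k),
                 as.integer(stride), as.integer(pad))
  ag_op(r$out, list(x), function() {
    idx <- r$idx
    function(g) {
      gx <- k_maxpool_bwd(g, idx, d)
      idx <<- NULL
      list(gx)
    }
  })
}

op_bilinear <- function(x, oh, ow) {
  d <- dims4(x$value)
  out <- k_bilinear(x$value, d, as.integer(oh), as.integer(ow))
  ag_op(out, list(x), function() {
    function(g) list(k_bilinear_bwd(g, d, as.integer(oh), as.integer(ow)))
  })
}

op_adaptive_avgpool <- function(x, bh, bw = bh) {
  d <- dims4(x$value)
  out <- k_adaptive_avgpool(x$value, d, as.integer(bh), as.integer(bw))
  ag_op(out, list(x), function() {
    function(g) list(k_adaptive_avgpool_bwd(g, d, as.integer(bh),
                                            as.integer(bw)))
  })
}

## Softmax over the spatial positions of a single-channel map (H, W, N, 1).
op_spatial_softmax <- function(x) {
  d <- dims4(x$value)
  stopifnot(d[4] == 1L)
  hw <- d[1] * d[2]
  Z <- x$value
  dim(Z) <- c(hw, d[3])
  Z <- Z - rep(apply(Z, 2, max), each = hw)
  E <- exp(Z)
  A <- E / rep(colSums(E), each = hw)
  out <- A
  dim(out) <- d
  ag_op(out, list(x), function() {
    force(A)
    function(g) {
      G <- g
      dim(G) <- c(hw, d[3])
      s <- colSums(A * G)
      gx <- A * (G - rep(s, each = hw))
      dim(gx) <- d
      list(gx)
    }
  })
}

## Attention pooling: context[n, c] = sum_hw x[h, w, n, c] * a[h, w, n, 1].
## Returns a (1, 1, N, C) node.
op_attention_pool <- function(x, a) {
  d <- dims4(x$value)
  hw <- d[1] * d[2]
  N <- d[3]; C <- d[4]
  X <- aperm(array(x$value, c(hw, N, C)), c(1, 3, 2))  # hw x C x N
  A <- a$value
  dim(A) <- c(hw, N)
  ct <- matrix(0, N, C)
  for (n in seq_len(N)) ct[n, ] <- crossprod(X[, , n, drop = TRUE], A[, n])
  dim(ct) <- c(1L, 1L, N, C)
  ag_op(ct, list(x, a), function() {
    force(X); force(A)
    function(g) {
      Gm <- matrix(g, N, C)
      gx <- array(0, c(hw, N, C))
      ga <- matrix(0, hw, N)
      for (n in seq_len(N)) {
        gx[, n, ] <- outer(A[, n], Gm[n, ])
        ga[, n] <- matrix(X[, , n], hw, C) %*% Gm[n, ]
      }
      dim(gx) <- d
      dim(ga) <- c(d[1], d[2], N, 1L)
      X <<- NULL
      list(gx, ga)
    }
  })
}

## Broadcast a (1, 1, N, C) context over space and add it to x (H, W, N, C):
## the channel-wise summation that closes the global-context block.
op_broadcast_add <- function(x, v) {
  d <- dims4(x$value)
  dv <- dims4(v$value)
  stopifnot(dv[1] == 1L, dv[2] == 1L, dv[3] == d[3], dv[4] == d[4])
  hw <- d[1] * d[2]
  out <- x$value + rep(as.vector(v$value), each = hw)
  ag_op(out, list(x, v), function() {
    function(g) {
      gv <- colSums(matrix(g, hw, d[3] * d[4]))
      dim(gv) <- dv
      list(g, gv)
    }
  })
}

## Layer normalization of a (1, 1, N, C) vector over its channel axis, with
## learnable per-channel affine.
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dims4(x$value)
  stopifnot(d[1] == 1L, d[2] == 1L)
  N <- d[3]; C <- d[4]
  X <- matrix(x$value, N, C)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * rep(gamma$value, each = N) + rep(beta$value, each = N)
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function() {
    force(xhat); force(inv)
    function(g) {
      G <- matrix(g, N, C)
      dgamma <- colSums(G * xhat)
      dbeta <- colSums(G)
      Gs <- G * rep(gamma$value, each = N)
      gx <- inv * (Gs - rowMeans(Gs) - xhat * rowMeans(Gs * xhat))
      dim(gx) <- d
      list(gx, dgamma, dbeta)
    }
  })
}
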