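# Finite-difference validation of the autograd engine's core operators.
# Everything downstream (blocks, network, training) rests on these adjoints.

num_grad <- function(f, x, eps = 1e-6) {
  g <- as.vector(x) * 0
  for (i in seq_along(g)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  dim(g) <- dim(x)
  g
}

test_that("convolution adjoints match finite differences", {
  set.seed(31)
  x <- array(rnorm(5 * 4 * 2 * 3), c(5, 4, 2, 3))
  w <- ag_param(matrix(rnorm(9 * 3 * 2) * 0.3, 27, 2))
  b <- ag_param(rnorm(2))
  R <- array(rnorm(5 * 4 * 2 * 2), c(5, 4, 2, 2))
  xn <- ag_node(x, requires = TRUE)
  out <- op_conv2d(xn, w, b, 3L, 3L)
  ag_backward(out, R)
  f <- function(v) sum(op_conv2d(ag_node(v), w, b, 3L, 3L)$value * R)
  expect_equal(xn$grad, num_grad(f, x), tolerance = 1e-6)
  fw <- function(v) sum(op_conv2d(ag_node(x), ag_param(v), b, 3L, 3L)$value * R)
  expect_equal(unname(as.vector(w$grad)), as.vector(num_grad(fw, w$value)),
               tolerance = 1e-6)
  # 1x1 fast path agrees with the general kernel
  w1 <- ag_param(matrix(rnorm(3 * 2), 3, 2))
  o1 <- op_conv2d(ag_node(x), w1, b, 1L, 1L)
  oref <- op_conv2d(ag_node(x), w1, b, 1L, 1L, stride = 1L, pad = 0L)
  expect_equal(o1$value, oref$value)
  # even kernels have no same-padding
  expect_error(op_conv2d(ag_node(x), w, b, 4L, 4L), "odd")
})

test_that("transposed convolution upscales x2 and its adjoint is exact", {
  set.seed(32)
  x <- array(rnorm(5 * 4 * 2 * 3), c(5, 4, 2, 3))
  w <- ag_param(matrix(rnorm(16 * 2 * 3) * 0.3, 32, 3))
  b <- ag_param(rnorm(2))
  xn <- ag_node(x, requires = TRUE)
  out <- op_conv_transpose2d(xn, w, b)
  expect_identical(dim(out$value)[1:2], c(10L, 8L))
  R <- array(rnorm(length(out$value)), dim(out$value))
  ag_backward(out, R)
  f <- function(v) sum(op_conv_transpose2d(ag_node(v), w, b)$value * R)
  expect_equal(xn$grad, num_grad(f, x), tolerance = 1e-6)
})

test_that("normalization and resampling adjoints match finite differences", {
  set.seed(33)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  # batch norm (training mode)
  st <- new.env(); st$running_mean <- rep(0, 3); st$running_var <- rep(1, 3)
  gm <- ag_param(runif(3, 0.5, 1.5)); bt <- ag_param(rnorm(3))
  xn <- ag_node(x, requires = TRUE)
  R <- array(rnorm(length(x)), dim(x))
  ag_backward(op_batchnorm(xn, gm, bt, st, TRUE), R)
  fbn <- function(v) {
    s <- new.env(); s$running_mean <- rep(0, 3); s$running_var <- rep(1, 3)
    sum(op_batchnorm(ag_node(v), gm, bt, s, TRUE)$value * R)
  }
  expect_equal(xn$grad, num_grad(fbn, x), tolerance = 1e-4)
  # bilinear upsampling
  xn <- ag_node(x, requires = TRUE)
  out <- op_bilinear(xn, 7L, 9L)
  R2 <- array(rnorm(length(out$value)), dim(out$value))
  ag_backward(out, R2)
  fb <- function(v) sum(op_bilinear(ag_node(v), 7L, 9L)$value * R2)
  expect_equal(xn$grad, num_grad(fb, x), tolerance = 1e-6)
  # max pooling routes gradient to the argmax
  xn <- ag_node(x, requires = TRUE)
  out <- op_maxpool(xn, 2L, stride = 2L)
  R3 <- array(rnorm(length(out$value)), dim(out$value))
  ag_backward(out, R3)
  fm <- function(v) sum(op_maxpool(ag_node(v), 2L, 2L)$value * R3)
  expect_equal(xn$grad, num_grad(fm, x), tolerance = 1e-6)
})

test_that("grad recording can be disabled and graphs stay per-call", {
  x <- array(rnorm(16), c(2, 2, 1, 4))
  w <- ag_param(matrix(rnorm(4), 4, 1))
  b <- ag_param(0)
  out <- ag_no_grad(op_conv2d(ag_node(x), w, b, 1L, 1L))
  expect_false(out$requires)
  expect_null(out$bwd)
})
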