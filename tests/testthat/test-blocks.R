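test_that("context gating follows the sigmoid-gate formula", {
  set.seed(11)
  x <- rand_fm(5, 5, 4)
  C <- 4L
  # zero parameters: every gate is sigmoid(0) = 0.5
  expect_equal(context_gate(x, list(weight = matrix(0, C, C),
                                    bias = rep(0, C))),
               0.5 * x)
  # saturated bias: gates approach 1, output approaches the input
  sat <- context_gate(x, list(weight = matrix(0, C, C), bias = rep(30, C)))
  expect_lt(max(abs(sat - x)), 1e-10)
  # random parameters against the elementwise loop oracle
  W <- matrix(rnorm(C * C), C, C)
  b <- rnorm(C)
  got <- context_gate(x, list(weight = W, bias = b))
  expect_equal(got, oracle_context_gate(x, W, b), tolerance = 1e-12)
  # gates strictly inside (0, 1): |out| < |in| wherever in != 0
  gates <- got / x
  expect_true(all(gates > 0 & gates < 1))
  expect_error(context_gate(x, list(weight = matrix(0, 3, 3),
                                    bias = rep(0, 3))),
               "channels")
})

test_that("CGR block: zero-weight identity, shape preservation, even-kernel error", {
  set.seed(12)
  cfg <- block_config(8, gca_bottleneck_ratio = 4, seed = 3)
  m <- cgr_module(cfg)
  zero_params(m)
  x <- rand_fm(6, 7, 8)
  # each of the four paths gates by sigmoid(0) = 0.5: out = x + 4 * 0.5 x
  expect_equal(cgr_block(x, cfg, module = m), 3 * x, tolerance = 1e-12)
  # shape preserved on a non-square map (channels x 17 x 23 contract)
  y <- rand_fm(17, 23, 8)
  expect_identical(dim(cgr_block(y, cfg)), dim(y))
  expect_error(block_config(8, cgr_kernel_sizes = c(2, 4)), "odd")
  expect_error(cgr_block(rand_fm(4, 4, 6), cfg), "channels")
})

test_that("gradient flows through all four CGR paths (finite differences)", {
  set.seed(13)
  cfg <- block_config(4, cgr_bottleneck_ratio = 2, gca_bottleneck_ratio = 2,
                      seed = 7)
  m <- cgr_module(cfg)
  x <- ag_node(array(rnorm(4 * 4 * 1 * 4), c(4, 4, 1, 4)), requires = TRUE)
  R <- array(rnorm(4 * 4 * 1 * 4), c(4, 4, 1, 4))
  out <- m$forward(x)
  ag_backward(out, R)
  eps <- 1e-6
  for (path in 1:4) {
    nm <- sprintf("cgr.path%d.conv2.b", path)
    p <- m$ctx$params[[nm]]
    expect_false(is.null(p$grad))
    expect_gt(max(abs(p$grad)), 0)
    # numeric check on the first bias coordinate of each path
    v0 <- p$value
    f <- function(b1) {
      p$value[1] <- b1
      on.exit(p$value <- v0)
      sum(m$forward(ag_node(x$value))$value * R)
    }
    num <- (f(v0[1] + eps) - f(v0[1] - eps)) / (2 * eps)
    expect_equal(p$grad[1], num, tolerance = 1e-5)
  }
})

test_that("GCA block: residual identity, context vector, softmax normalization", {
  set.seed(14)
  cfg <- block_config(16, seed = 21)
  x <- rand_fm(6, 6, 16)
  # final transform is zero-initialized: a fresh block is an exact identity
  expect_equal(gca_block(x, cfg), x, tolerance = 1e-12)
  m <- gca_module(cfg)
  # spatially constant input: context = the constant, whatever the weights
  v <- rnorm(16)
  const <- array(rep(v, each = 36), c(6, 6, 1, 16))
  ct <- ag_no_grad(m$context(ag_node(const)))
  expect_equal(as.vector(ct$value), v, tolerance = 1e-10)
  # random input: context matches the loop-based attention oracle
  wa <- as.vector(m$ctx$params[["gca.attn.w"]]$value)
  ba <- m$ctx$params[["gca.attn.b"]]$value
  xb <- x; dim(xb) <- c(6, 6, 1, 16)
  got <- as.vector(ag_no_grad(m$context(ag_node(xb)))$value)
  expect_equal(got, oracle_gca_context(x, wa, ba), tolerance = 1e-10)
  # attention weights sum to 1 over positions
  a <- ag_no_grad(op_spatial_softmax(ag_node(
    array(rnorm(5 * 7 * 2), c(5, 7, 2, 1)))))
  sums <- colSums(matrix(a$value, 35, 2))
  expect_equal(sums, c(1, 1), tolerance = 1e-5)
  expect_error(block_config(10, gca_bottleneck_ratio = 16), "divisible")
})

test_that("MRP block: channel arithmetic, constant paths, window-max oracle", {
  set.seed(15)
  cfg <- block_config(16, seed = 2)
  x <- rand_fm(8, 8, 16)
  y <- mrp_block(x, cfg)
  expect_identical(dim(y), c(8L, 8L, 16L + 4L))
  expect_equal(y[, , 1:16], x)  # the input rides along unchanged
  # max pooling of a constant is the constant on every path
  m <- mrp_module(cfg)
  for (i in 1:4) {
    m$ctx$params[[sprintf("mrp.pool%d.conv.w", i)]]$value <-
      matrix(1 / 16, 16, 1)
    m$ctx$params[[sprintf("mrp.pool%d.conv.b", i)]]$value <- 0
  }
  const <- array(2, c(7, 7, 16))
  yc <- mrp_block(const, cfg, module = m)
  for (ch in 4:7) expect_equal(yc[, , ch], matrix(2, 7, 7), tolerance = 1e-12)
  # pooled values match the explicit sliding-window max oracle
  for (k in c(2L, 3L, 5L, 7L)) {
    xb <- rand_fm(8, 8, 4); dim(xb) <- c(8, 8, 1, 4)
    pooled <- ag_no_grad(op_maxpool(ag_node(xb), k, stride = k))$value
    dim(pooled) <- dim(pooled)[c(1, 2, 4)]
    ref <- oracle_window_max(array(xb, c(8, 8, 4)), k)
    expect_equal(pooled, ref, tolerance = 0)
  }
  expect_error(mrp_block(rand_fm(4, 4, 16), cfg), "smaller than")
})

test_that("CAGP bottleneck: fusion width, finiteness, seeded determinism", {
  cfg <- block_config(16, fusion_channels = 12, seed = 9)
  x <- rand_fm(8, 8, 16)
  y1 <- cagp_module(x, cfg)
  expect_identical(dim(y1), c(8L, 8L, 12L))
  y2 <- cagp_module(x, cfg)
  expect_identical(y1, y2)  # same config seed, bit-identical modules
  m <- cagp_modules(cfg)
  zero_params(m, "cgr|gca|mrp")  # fusion keeps its init
  yz <- cagp_module(x, cfg, module = m)
  expect_true(all(is.finite(yz)))
  # pooling windows larger than the map are clamped inside the module
  small <- rand_fm(2, 2, 16)
  expect_identical(dim(cagp_module(small, cfg)), c(2L, 2L, 12L))
})

test_that("decoder stage doubles resolution and zeroes propagate", {
  set.seed(16)
  x <- rand_fm(8, 8, 32)
  skip <- rand_fm(16, 16, 16)
  out <- decoder_block(x, skip, out_channels = 24, seed = 4)
  expect_identical(dim(out), c(16L, 16L, 24L))
  # misaligned skip raises an error naming both shapes
  expect_error(decoder_block(x, rand_fm(15, 16, 16), 24, seed = 4),
               "15x16.*8x8")
  # zero inputs through a zeroed stage collapse to zeros, and batch norm
  # centres a bias-only (spatially constant) signal to exact zero mean
  m <- gcunet:::decoder_stage_module(gcunet:::new_ctx(), "dec", 32, 16, 24)
  zero_params(list(ctx = m$ctx))
  z <- ag_no_grad(m$forward(ag_node(array(0, c(8, 8, 1, 32))),
                            ag_node(array(0, c(16, 16, 1, 16))),
                            training = TRUE))
  expect_equal(max(abs(z$value)), 0)
  st <- new.env(); st$running_mean <- rep(0, 3); st$running_var <- rep(1, 3)
  bias_only <- array(rep(rnorm(3), each = 36), c(6, 6, 1, 3))
  bn <- ag_no_grad(op_batchnorm(ag_node(bias_only), ag_param(rep(1, 3)),
                                ag_param(rep(0, 3)), st, training = TRUE))
  expect_equal(max(abs(bn$value)), 0)
  # x2 upsampling composes across pyramid levels 8 -> 16 -> 32 -> 64
  h <- rand_fm(8, 8, 8)
  for (side in c(16L, 32L, 64L)) {
    h <- decoder_block(h, rand_fm(side, side, 4), 8, seed = side)
    expect_identical(dim(h), c(side, side, 8L))
  }
})

test_that("RCA module: identity at zero init, pyramid means", {
  set.seed(17)
  x <- rand_fm(12, 10, 6)
  # pyramid convolutions are zero-initialized: exact identity
  expect_equal(rca_module(x, seed = 1), x, tolerance = 1e-12)
  # constant input: adaptive averaging returns the constant at every bin
  const <- array(3.5, c(9, 9, 2, 1))
  for (b in c(1L, 2L, 3L, 6L)) {
    p <- ag_no_grad(op_adaptive_avgpool(ag_node(const), b, b))$value
    expect_equal(range(p), c(3.5, 3.5))
  }
  # bin-1 path equals the per-channel global mean
  xb <- rand_fm(7, 7, 5); dim(xb) <- c(7, 7, 1, 5)
  p1 <- as.vector(ag_no_grad(op_adaptive_avgpool(ag_node(xb), 1, 1))$value)
  expect_equal(p1, apply(array(xb, c(7, 7, 5)), 3, mean), tolerance = 1e-12)
  expect_error(rca_module(rand_fm(4, 4, 6), bins = c(1, 2, 3, 6), seed = 1),
               "smaller than")
})

test_that("shape preservation holds across randomized shapes", {
  set.seed(18)
  for (i in 1:6) {
    H <- sample(3:12, 1); W <- sample(3:12, 1)
    cfg <- block_config(16, mrp_pool_sizes = c(2L, 3L),
                        rca_bins = c(1L, 2L), seed = i)
    x <- rand_fm(H, W, 16)
    expect_identical(dim(cgr_block(x, cfg)), dim(x))
    expect_identical(dim(gca_block(x, cfg)), dim(x))
    expect_identical(dim(rca_module(x, bins = c(1L, 2L), seed = i)), dim(x))
    g <- context_gate(x, list(weight = matrix(rnorm(256), 16), bias = rnorm(16)))
    expect_identical(dim(g), dim(x))
  }
})
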