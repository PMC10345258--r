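test_that("model builds, forward shapes and range hold, seeding is exact", {
  m1 <- build_model(model_config(seed = 5))
  m2 <- build_model(model_config(seed = 5))
  v1 <- get_param_values(m1)
  v2 <- get_param_values(m2)
  expect_identical(v1, v2)  # bit-identical seeded initialization
  np <- n_params(m1)
  x64 <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- forward(m1, x64)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(min(p) >= 0 && max(p) <= 1)
  # eval-mode forward is deterministic
  expect_identical(p, forward(m1, x64))
  # zero image stays finite
  expect_true(all(is.finite(forward(m1, array(0, c(64, 64, 3))))))
  # non-square input
  p2 <- forward(m1, array(runif(96 * 128 * 3), c(96, 128, 3)))
  expect_identical(dim(p2), c(96L, 128L))
  # parameter count is invariant to input size
  expect_identical(n_params(m1), np)
  # indivisible spatial dims are rejected with advice
  expect_error(forward(m1, array(0, c(50, 64, 3))), "divisible by 32")
  # pretrained weights are unavailable offline
  expect_error(build_model(model_config(pretrained = TRUE)), "offline")
})

test_that("segmentation loss follows its formula and the loop oracle", {
  ones <- matrix(1, 4, 4)
  expect_lt(segmentation_loss(ones - 1e-9, ones), 1e-6)
  # fully disjoint binary prediction: the Dice term saturates near 1
  t <- matrix(rep(c(1, 0), 8), 4, 4)
  expect_equal(segmentation_loss(1 - t, t, bce_weight = 0, dice_weight = 1,
                                 eps = 1e-9), 1, tolerance = 1e-6)
  set.seed(41)
  p <- matrix(runif(64, 0.01, 0.99), 8, 8)
  tt <- matrix(rbinom(64, 1, 0.4), 8, 8)
  # hand-rolled elementwise reference for both terms
  bce_ref <- 0
  for (i in 1:8) for (j in 1:8) {
    bce_ref <- bce_ref - (tt[i, j] * log(p[i, j]) +
                            (1 - tt[i, j]) * log(1 - p[i, j]))
  }
  bce_ref <- bce_ref / 64
  dice_ref <- 1 - (2 * sum(p * tt) + 1) / (sum(p) + sum(tt) + 1)
  expect_equal(segmentation_loss(p, tt, 2, 3), 2 * bce_ref + 3 * dice_ref,
               tolerance = 1e-12)
  expect_error(segmentation_loss(p, matrix(0, 3, 3)), "shapes differ")
  # the training-loop gradient agrees with finite differences of the loss
  z <- matrix(rnorm(16), 4, 4)
  t4 <- matrix(rbinom(16, 1, 0.5), 4, 4)
  lg <- gcunet:::loss_value_grad(z, t4)
  eps <- 1e-6
  for (i in c(1L, 7L, 16L)) {
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (gcunet:::loss_value_grad(zp, t4)$value -
              gcunet:::loss_value_grad(zm, t4)$value) / (2 * eps)
    expect_equal(lg$grad[i], num, tolerance = 1e-5)
  }
})

test_that("one small-enough gradient step strictly decreases the loss", {
  model <- build_model(model_config(seed = 8))
  s <- generate_scene(desk_spec(1))
  b <- stack_samples(list(s))
  z0 <- model$forward_logits(ag_node(b$x), training = FALSE)
  lg0 <- gcunet:::loss_value_grad(z0$value, b$t)
  ag_zero_grad(model$ctx$params)
  zt <- model$forward_logits(ag_node(b$x), training = TRUE)
  ag_backward(zt, gcunet:::loss_value_grad(zt$value, b$t)$grad)
  decreased <- FALSE
  for (lr in c(1e-2, 1e-3, 1e-4, 1e-5)) {
    saved <- gcunet:::ctx_state(model$ctx)
    for (p in model$ctx$params) {
      if (!is.null(p$grad)) p$value <- p$value - lr * p$grad
    }
    z1 <- model$forward_logits(ag_node(b$x), training = FALSE)
    l1 <- gcunet:::loss_value_grad(z1$value, b$t)$value
    gcunet:::ctx_restore(model$ctx, saved)
    if (l1 < lg0$value) { decreased <- TRUE; break }
  }
  expect_true(decreased)
})

test_that("the 121-layer encoder variant builds and preserves shape", {
  m <- build_model(model_config(encoder_name = "densenet121", seed = 0))
  p <- forward(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_identical(dim(p), c(64L, 64L))
  expect_true(min(p) >= 0 && max(p) <= 1)
  expect_gt(n_params(m), 4e7)  # the canonical configuration is much larger
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  m <- build_model(model_config(seed = 3))
  dir <- withr::local_tempdir()
  pth <- file.path(dir, "ck.rds")
  save_checkpoint(m, pth, extra = list(epoch = 0L))
  lk <- load_checkpoint(pth)
  expect_identical(get_param_values(lk$model), get_param_values(m))
  other <- build_model(model_config(seed = 3, decoder_widths = c(64, 32, 16, 16)))
  expect_error(load_checkpoint(pth, other), "different model configuration")
})
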