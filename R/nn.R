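## Layer constructors. A "ctx" (module context) collects every parameter and
## buffer under a hierarchical name so checkpoints and the Adam loop see a
## flat, deterministically ordered list. Parameter initialization draws from
## R's RNG in creation order, so a single set.seed() makes builds repeatable.

new_ctx <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e$buffers <- list()  # environments with non-trained state (BN running stats)
  e
}

ctx_reg_param <- function(ctx, name, node) {
  if (!is.null(ctx$params[[name]])) stop("duplicate parameter name: ", name)
  node$name <- name
  ctx$params[[name]] <- node
  node
}

ctx_reg_buffer <- function(ctx, name, env) {
  ctx$buffers[[name]] <- env
  env
}

## Kaiming-uniform fan-in initialization (the convention of the major DL
## frameworks for conv layers feeding ReLU).
kaiming_uniform <- function(n, fan_in, gain = sqrt(2)) {
  bound <- gain * sqrt(3 / fan_in)
  stats::runif(n, -bound, bound)
}

## k x k convolution layer; weight rows ordered (dh, dw, cin) per k_im2col.
nn_conv <- function(ctx, name, cin, cout, k, stride = 1L, pad = NULL,
                    zero_init = FALSE) {
  fan_in <- cin * k * k
  if (zero_init) {
    wv <- matrix(0, k * k * cin, cout)
    bv <- numeric(cout)
  } else {
    wv <- matrix(kaiming_uniform(k * k * cin * cout, fan_in), k * k * cin, cout)
    bv <- stats::runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  }
  w <- ctx_reg_param(ctx, paste0(name, ".w"), ag_param(wv))
  b <- ctx_reg_param(ctx, paste0(name, ".b"), ag_param(bv))
  list(w = w, b = b,
       fwd = function(x) op_conv2d(x, w, b, k, k, stride, pad))
}

## 4x4 stride-2 transposed convolution (the decoder upscaler).
nn_convT <- function(ctx, name, cin, cout, k = 4L, stride = 2L, pad = 1L) {
  fan_in <- cin * k * k / (stride * stride)
  wv <- matrix(kaiming_uniform(k * k * cout * cin, fan_in), k * k * cout, cin)
  bv <- stats::runif(cout, -1 / sqrt(fan_in), 1 / sqrt(fan_in))
  w <- ctx_reg_param(ctx, paste0(name, ".w"), ag_param(wv))
  b <- ctx_reg_param(ctx, paste0(name, ".b"), ag_param(bv))
  list(w = w, b = b,
       fwd = function(x) op_conv_transpose2d(x, w, b, k, stride, pad))
}

nn_bn <- function(ctx, name, C, momentum = 0.1) {
  gamma <- ctx_reg_param(ctx, paste0(name, ".gamma"), ag_param(rep(1, C)))
  beta <- ctx_reg_param(ctx, paste0(name, ".beta"), ag_param(rep(0, C)))
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  ctx_reg_buffer(ctx, paste0(name, ".stats"), st)
  list(gamma = gamma, beta = beta, stats = st,
       fwd = function(x, training) {
         op_batchnorm(x, gamma, beta, st, training, momentum)
       })
}

nn_layernorm <- function(ctx, name, C) {
  gamma <- ctx_reg_param(ctx, paste0(name, ".gamma"), ag_param(rep(1, C)))
  beta <- ctx_reg_param(ctx, paste0(name, ".beta"), ag_param(rep(0, C)))
  list(gamma = gamma, beta = beta,
       fwd = function(x) op_layernorm(x, gamma, beta))
}

## --- parameter utilities ---------------------------------------------------

#' Extract all parameter values of a model or block as a named list
#' @param obj an object with a `ctx` module context (model or block).
#' @return named list of numeric arrays.
#' @export
get_param_values <- function(obj) {
  lapply(obj$ctx$params, function(p) p$value)
}

#' Overwrite parameter values from a named list
#' @param obj an object with a `ctx` module context.
#' @param values named list as produced by [get_param_values()].
#' @export
set_param_values <- function(obj, values) {
  for (nm in names(values)) {
    p <- obj$ctx$params[[nm]]
    if (is.null(p)) stop("unknown parameter: ", nm)
    stopifnot(length(p$value) == length(values[[nm]]))
    v <- values[[nm]] + 0  # copy: parameter memory is mutated in place
    dim(v) <- dim(p$value)
    p$value <- v
  }
  invisible(obj)
}

#' Set parameters matching a name pattern to zero
#'
#' Convenience for exercising the analytic identities of the attention
#' blocks (zeroed transforms reduce them to identity maps).
#'
#' @param obj object with a `ctx`.
#' @param pattern regular expression matched against parameter names;
#'   default zeroes everything.
#' @export
zero_params <- function(obj, pattern = ".") {
  for (nm in names(obj$ctx$params)) {
    if (grepl(pattern, nm)) {
      p <- obj$ctx$params[[nm]]
      p$value <- p$value * 0
    }
  }
  invisible(obj)
}

#' Total number of trainable parameters
#' @param obj object with a `ctx`.
#' @return integer count.
#' @export
n_params <- function(obj) {
  sum(vapply(obj$ctx$params, function(p) length(p$value), numeric(1)))
}

## deep copies: the Adam kernel updates parameter memory in place, so state
## snapshots must not alias the live values
ctx_state <- function(ctx) {
  cp <- function(v) if (is.null(v)) NULL else v + 0
  list(params = lapply(ctx$params, function(p) cp(p$value)),
       adam_m = lapply(ctx$params, function(p) cp(p$adam_m)),
       adam_v = lapply(ctx$params, function(p) cp(p$adam_v)),
       buffers = lapply(ctx$buffers, function(b) as.list(b)))
}

ctx_restore <- function(ctx, state) {
  stopifnot(identical(names(state$params), names(ctx$params)))
  cp <- function(v) if (is.null(v)) NULL else v + 0
  for (nm in names(ctx$params)) {
    p <- ctx$params[[nm]]
    v <- cp(state$params[[nm]])
    dim(v) <- dim(p$value)
    p$value <- v
    p$adam_m <- cp(state$adam_m[[nm]])
    p$adam_v <- cp(state$adam_v[[nm]])
  }
  for (nm in names(state$buffers)) {
    b <- ctx$buffers[[nm]]
    for (f in names(state$buffers[[nm]])) assign(f, state$buffers[[nm]][[f]], envir = b)
  }
  invisible(ctx)
}

## batch-axis helpers: public arrays are H x W x C (single image) or
## H x W x N x C (batch); a length-1 batch axis is inserted/removed
## transparently (pure dim relabelling in this layout).
to_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d[1], d[2], 1L, d[3])
    attr(x, "gcu_squeeze") <- TRUE
  } else if (length(d) != 4L) {
    stop("expected an H x W x C or H x W x N x C array", call. = FALSE)
  }
  x
}

from_batch <- function(v, squeeze) {
  attr(v, "gcu_squeeze") <- NULL
  if (squeeze) {
    d <- dim(v)
    stopifnot(d[3] == 1L)
    dim(v) <- c(d[1], d[2], d[4])
  }
  v
}

## strip the squeeze marker before computation so it cannot propagate into
## results through R's attribute-preserving arithmetic
drop_marker <- function(x) {
  attr(x, "gcu_squeeze") <- NULL
  x
}
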