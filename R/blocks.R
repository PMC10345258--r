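## The bespoke architectural blocks of GC-UNet: context gating (CGR),
## global-context attention (GCA), multipath residual pooling (MRP), the
## fused bottleneck (CAGP) and the decoder-side units (decoder stage, RCA).
##
## Each block exists in two forms: a *module* constructor (`*_module()`,
## returning parameters plus a forward closure; used by the full network)
## and a functional wrapper with the block's contract signature that builds
## a seeded module on the fly and applies it to a plain array.

#' Block hyperparameter configuration
#'
#' Collects the tunable sizes of the attention/pooling blocks. Defaults are
#' the published configuration: context-gating kernel sizes 3/5/7/9, max
#' pooling windows 2/3/5/7, global-context bottleneck ratio 16.
#'
#' @param channels number of feature channels the blocks operate on.
#' @param cgr_kernel_sizes odd kernel sizes of the four gating paths.
#' @param mrp_pool_sizes max-pooling window sizes.
#' @param gca_bottleneck_ratio channel reduction ratio r of the
#'   global-context transform; `channels` must be divisible by it.
#' @param cgr_bottleneck_ratio channel reduction inside each gating path
#'   (first convolution maps C to C/ratio); keeps the large-kernel paths
#'   affordable on CPU.
#' @param rca_bins pyramid-pooling bin sizes of the decoder attention.
#' @param fusion_channels output width of the bottleneck fusion convolution.
#' @param seed optional integer; seeds parameter initialization of the
#'   functional block wrappers.
#' @return a list of class `gcu_block_config`.
#' @export
block_config <- function(channels,
                         cgr_kernel_sizes = c(3L, 5L, 7L, 9L),
                         mrp_pool_sizes = c(2L, 3L, 5L, 7L),
                         gca_bottleneck_ratio = 16L,
                         cgr_bottleneck_ratio = 8L,
                         rca_bins = c(1L, 2L, 3L, 6L),
                         fusion_channels = channels,
                         seed = NULL) {
  stopifnot(channels >= 1)
  if (any(cgr_kernel_sizes %% 2L == 0L)) {
    stop("cgr_kernel_sizes must be odd (same-padding undefined for even sizes)",
         call. = FALSE)
  }
  if (channels %% gca_bottleneck_ratio != 0L) {
    stop(sprintf("channels (%d) not divisible by gca_bottleneck_ratio (%d)",
                 channels, gca_bottleneck_ratio), call. = FALSE)
  }
  structure(list(channels = as.integer(channels),
                 cgr_kernel_sizes = as.integer(cgr_kernel_sizes),
                 mrp_pool_sizes = as.integer(mrp_pool_sizes),
                 gca_bottleneck_ratio = as.integer(gca_bottleneck_ratio),
                 cgr_bottleneck_ratio = as.integer(cgr_bottleneck_ratio),
                 rca_bins = as.integer(rca_bins),
                 fusion_channels = as.integer(fusion_channels),
                 seed = seed),
            class = "gcu_block_config")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

apply_block <- function(module, input, ...) {
  x <- to_batch(input)
  squeeze <- isTRUE(attr(x, "gcu_squeeze"))
  out <- ag_no_grad(module$forward(as_node(drop_marker(x)), ...))
  from_batch(out$value, squeeze)
}

check_channels <- function(input, channels) {
  d <- dim(to_batch(input))
  if (d[4] != channels) {
    stop(sprintf("input has %d channels but the block is configured for %d",
                 d[4], channels), call. = FALSE)
  }
}

## --- context gate -----------------------------------------------------------

#' Multiplicative context gating
#'
#' Scales each feature by a learned sigmoid gate: `out = x * sigmoid(W x + a)`
#' with W applied as a 1x1 convolution (a per-pixel channel-affine map).
#' Gates lie strictly in (0, 1), so the operation attenuates but never
#' flips or inflates features.
#'
#' @param input H x W x C (or H x W x N x C) numeric array.
#' @param params list with `weight` (C x C matrix, rows = input channels,
#'   columns = output channels) and `bias` (length C).
#' @return array of the same shape as `input`.
#' @export
context_gate <- function(input, params) {
  x <- to_batch(input)
  squeeze <- isTRUE(attr(x, "gcu_squeeze"))
  C <- dim(x)[4]
  w <- params$weight
  b <- params$bias
  if (!is.matrix(w) || nrow(w) != C || ncol(w) != C || length(b) != C) {
    stop(sprintf(
      "gating params shaped for %s channels do not match input with %d channels",
      if (is.matrix(w)) nrow(w) else "?", C), call. = FALSE)
  }
  out <- ag_no_grad({
    xn <- as_node(drop_marker(x))
    gate <- op_sigmoid(op_conv2d(xn, as_node(w), as_node(b), 1L, 1L))
    op_mul(xn, gate)
  })
  from_batch(out$value, squeeze)
}

## --- CGR --------------------------------------------------------------------

#' @rdname cgr_block
#' @param ctx optional module context to register parameters into.
#' @param name parameter name prefix.
#' @export
cgr_module <- function(config, ctx = new_ctx(), name = "cgr") {
  C <- config$channels
  cb <- max(1L, C %/% config$cgr_bottleneck_ratio)
  paths <- lapply(seq_along(config$cgr_kernel_sizes), function(i) {
    k <- config$cgr_kernel_sizes[i]
    list(conv1 = nn_conv(ctx, sprintf("%s.path%d.conv1", name, i), C, cb, k),
         conv2 = nn_conv(ctx, sprintf("%s.path%d.conv2", name, i), cb, C, k))
  })
  forward <- function(x, training = FALSE) {
    gated <- lapply(paths, function(p) {
      a <- op_sigmoid(p$conv2$fwd(op_relu(p$conv1$fwd(x))))
      op_mul(a, x)
    })
    op_add(x, op_add_n(gated))
  }
  list(ctx = ctx, forward = forward, config = config)
}

#' Context gating residual block
#'
#' Four parallel gating paths at kernel sizes 3/5/7/9; each path runs two
#' same-padding convolutions (the first compresses channels, the second
#' restores them) and a sigmoid to produce attention weights that multiply
#' the input. The weighted maps are summed and added to a residual skip of
#' the input, so the block widens the receptive field while preserving
#' shape. With all path convolutions zeroed every gate equals 0.5 and the
#' output is exactly `3 * input`.
#'
#' @param input H x W x C (or H x W x N x C) numeric array.
#' @param config a [block_config()]; `config$channels` must equal the input
#'   channel count.
#' @param module optional pre-built module (from [cgr_module()]); built
#'   fresh (seeded by `config$seed`) when NULL.
#' @return array of the same shape as `input`.
#' @export
cgr_block <- function(input, config, module = NULL) {
  check_channels(input, config$channels)
  if (is.null(module)) module <- with_seed(config$seed, cgr_module(config))
  apply_block(module, input)
}

## --- GCA --------------------------------------------------------------------

#' @rdname gca_block
#' @param ctx optional module context.
#' @param name parameter name prefix.
#' @export
gca_module <- function(config, ctx = new_ctx(), name = "gca") {
  C <- config$channels
  Cr <- C %/% config$gca_bottleneck_ratio
  attn <- nn_conv(ctx, paste0(name, ".attn"), C, 1L, 1L)
  t1 <- nn_conv(ctx, paste0(name, ".transform1"), C, Cr, 1L)
  ln <- nn_layernorm(ctx, paste0(name, ".ln"), Cr)
  ## zero-initialized: the block starts as an exact identity map
  t2 <- nn_conv(ctx, paste0(name, ".transform2"), Cr, C, 1L, zero_init = TRUE)
  context <- function(x) {
    a <- op_spatial_softmax(attn$fwd(x))
    op_attention_pool(x, a)                     # (1,1,N,C) context vector
  }
  forward <- function(x, training = FALSE) {
    ct <- context(x)
    tr <- t2$fwd(op_relu(ln$fwd(t1$fwd(ct))))
    op_broadcast_add(x, tr)
  }
  list(ctx = ctx, forward = forward, context = context, config = config)
}

#' Global context attention block
#'
#' Pools the feature map into a single context vector using a learned
#' spatial-softmax attention map (a 1x1 convolution scores every position;
#' softmax over positions; the feature map is contracted against the
#' weights). The context vector passes through a channel bottleneck
#' (1x1 conv to C/r, layer normalization, ReLU, 1x1 conv back to C) and is
#' added to every spatial position. The final transform convolution is
#' zero-initialized, so a fresh block is an exact identity.
#'
#' @inheritParams cgr_block
#' @param module optional pre-built module from [gca_module()].
#' @return array of the same shape as `input`.
#' @export
gca_block <- function(input, config, module = NULL) {
  check_channels(input, config$channels)
  if (is.null(module)) module <- with_seed(config$seed, gca_module(config))
  apply_block(module, input)
}

## --- MRP --------------------------------------------------------------------

#' @rdname mrp_block
#' @param ctx optional module context.
#' @param name parameter name prefix.
#' @export
mrp_module <- function(config, ctx = new_ctx(), name = "mrp") {
  C <- config$channels
  convs <- lapply(seq_along(config$mrp_pool_sizes), function(i) {
    nn_conv(ctx, sprintf("%s.pool%d.conv", name, i), C, 1L, 1L)
  })
  forward <- function(x, training = FALSE, clamp = FALSE) {
    d <- dims4(x$value)
    sizes <- config$mrp_pool_sizes
    if (clamp) sizes <- pmin(sizes, min(d[1], d[2]))
    if (any(sizes > min(d[1], d[2]))) {
      stop(sprintf(
        "mrp: input %dx%d smaller than pooling window %d",
        d[1], d[2], max(sizes)), call. = FALSE)
    }
    maps <- lapply(seq_along(sizes), function(i) {
      p <- op_maxpool(x, sizes[i], stride = sizes[i])
      op_bilinear(convs[[i]]$fwd(p), d[1], d[2])
    })
    op_concat_c(c(list(x), maps))
  }
  list(ctx = ctx, forward = forward, config = config)
}

#' Multipath residual pooling block
#'
#' Max-pools the input at window sizes 2/3/5/7 (non-overlapping windows,
#' stride = window), compresses each pooled map to a single channel with a
#' 1x1 convolution, upsamples it bilinearly back to the input grid, and
#' concatenates the four context channels with the input. Output channels =
#' input channels + number of pooling paths; spatial size unchanged.
#'
#' @inheritParams cgr_block
#' @param module optional pre-built module from [mrp_module()].
#' @return array with `length(config$mrp_pool_sizes)` extra channels.
#' @export
mrp_block <- function(input, config, module = NULL) {
  check_channels(input, config$channels)
  if (is.null(module)) module <- with_seed(config$seed, mrp_module(config))
  apply_block(module, input)
}

## --- CAGP -------------------------------------------------------------------

#' @rdname cagp_module
#' @param ctx optional module context.
#' @param name parameter name prefix.
#' @export
cagp_modules <- function(config, ctx = new_ctx(), name = "cagp") {
  cgr <- cgr_module(config, ctx, paste0(name, ".cgr"))
  gca <- gca_module(config, ctx, paste0(name, ".gca"))
  mrp <- mrp_module(config, ctx, paste0(name, ".mrp"))
  cin <- config$channels + length(config$mrp_pool_sizes)
  fuse <- nn_conv(ctx, paste0(name, ".fuse"), cin, config$fusion_channels, 1L)
  bn <- nn_bn(ctx, paste0(name, ".fuse_bn"), config$fusion_channels)
  forward <- function(x, training = FALSE) {
    h <- cgr$forward(x, training)
    h <- gca$forward(h, training)
    ## pooling windows larger than the (deep, small) bottleneck map are
    ## clamped to its extent rather than failing
    h <- mrp$forward(h, training, clamp = TRUE)
    op_relu(bn$fwd(fuse$fwd(h), training))
  }
  list(ctx = ctx, forward = forward, config = config)
}

#' Context-aware gate pooling bottleneck
#'
#' The bottleneck applied to the deepest encoder feature map: context gating
#' residual block, then global context attention, then multipath residual
#' pooling, then a 1x1 fusion convolution (+ batch norm + ReLU) restoring a
#' configured channel width (`config$fusion_channels`). Spatial size is
#' preserved.
#'
#' @inheritParams cgr_block
#' @param module optional pre-built module from [cagp_modules()].
#' @param training logical; batch-norm mode.
#' @return array with `config$fusion_channels` channels.
#' @export
cagp_module <- function(input, config, module = NULL, training = FALSE) {
  check_channels(input, config$channels)
  if (is.null(module)) module <- with_seed(config$seed, cagp_modules(config))
  apply_block(module, input, training)
}

## --- decoder stage ----------------------------------------------------------

decoder_stage_module <- function(ctx, name, cin, cskip, cout) {
  up <- nn_convT(ctx, paste0(name, ".up"), cin, cout)
  conv1 <- nn_conv(ctx, paste0(name, ".conv1"), cout + cskip, cout, 3L)
  bn1 <- nn_bn(ctx, paste0(name, ".bn1"), cout)
  conv2 <- nn_conv(ctx, paste0(name, ".conv2"), cout, cout, 3L)
  bn2 <- nn_bn(ctx, paste0(name, ".bn2"), cout)
  forward <- function(x, skip, training = FALSE) {
    dx <- dims4(x$value)
    ds <- dims4(skip$value)
    if (ds[1] != 2L * dx[1] || ds[2] != 2L * dx[2]) {
      stop(sprintf(
        "decoder stage: skip %dx%d is not twice the input %dx%d",
        ds[1], ds[2], dx[1], dx[2]), call. = FALSE)
    }
    h <- op_concat_c(list(up$fwd(x), skip))
    h <- op_relu(bn1$fwd(conv1$fwd(h), training))
    op_relu(bn2$fwd(conv2$fwd(h), training))
  }
  list(ctx = ctx, forward = forward)
}

#' Decoder stage: learned x2 upsampling with skip fusion
#'
#' Upscales the incoming map with a 4x4 stride-2 transposed convolution,
#' concatenates the encoder skip (which must be exactly twice the input's
#' spatial size), and refines with two 3x3 convolutions, each followed by
#' batch normalization and ReLU. Output spatial size equals the skip's.
#'
#' @param input H x W x C array (decoder path).
#' @param skip 2H x 2W x Cs array (encoder skip).
#' @param out_channels channel width of the stage output.
#' @param seed optional seed for the fresh parameters.
#' @param training logical; batch-norm mode.
#' @return array of shape 2H x 2W x out_channels.
#' @export
decoder_block <- function(input, skip, out_channels, seed = NULL,
                          training = FALSE) {
  x <- to_batch(input)
  s <- to_batch(skip)
  squeeze <- isTRUE(attr(x, "gcu_squeeze"))
  m <- with_seed(seed, decoder_stage_module(new_ctx(), "dec",
                                            dim(x)[4], dim(s)[4],
                                            as.integer(out_channels)))
  out <- ag_no_grad(m$forward(as_node(drop_marker(x)),
                              as_node(drop_marker(s)), training))
  from_batch(out$value, squeeze)
}

## --- RCA --------------------------------------------------------------------

#' @rdname rca_module
#' @param channels feature channel count.
#' @param bins pyramid bin sizes.
#' @param ctx optional module context.
#' @param name parameter name prefix.
#' @export
rca_modules <- function(channels, bins = c(1L, 2L, 3L, 6L),
                        ctx = new_ctx(), name = "rca") {
  convs <- lapply(seq_along(bins), function(i) {
    ## zero-initialized: a fresh block is an exact identity
    nn_conv(ctx, sprintf("%s.bin%d.conv", name, i), channels, channels, 1L,
            zero_init = TRUE)
  })
  forward <- function(x, training = FALSE, clamp = FALSE) {
    d <- dims4(x$value)
    bs <- as.integer(bins)
    if (clamp) bs <- unique(pmin(bs, min(d[1], d[2])))
    if (any(bs > min(d[1], d[2]))) {
      stop(sprintf("rca: input %dx%d smaller than pyramid bin %d",
                   d[1], d[2], max(bs)), call. = FALSE)
    }
    maps <- lapply(seq_along(bs), function(i) {
      p <- op_adaptive_avgpool(x, bs[i], bs[i])
      op_bilinear(convs[[min(i, length(convs))]]$fwd(p), d[1], d[2])
    })
    op_add(x, op_add_n(maps))
  }
  list(ctx = ctx, forward = forward)
}

#' Residual context attention module
#'
#' Decoder-side refinement with a global context path and a local feature
#' path. The global path is a pyramid pooling structure: adaptive average
#' pooling to bin sizes 1/2/3/6, a 1x1 convolution per bin, bilinear
#' upsampling back to the input grid, and summation. The local path is the
#' identity. The two paths combine residually (`input + context`), so shape
#' is preserved and a zero-initialized block is an identity map.
#'
#' @param input H x W x C (or H x W x N x C) numeric array.
#' @param bins pyramid bin sizes; the input spatial extent must reach the
#'   largest bin.
#' @param seed optional seed for fresh parameters.
#' @param module optional pre-built module from [rca_modules()].
#' @return array of the same shape as `input`.
#' @export
rca_module <- function(input, bins = c(1L, 2L, 3L, 6L), seed = NULL,
                       module = NULL) {
  x <- to_batch(input)
  if (is.null(module)) {
    module <- with_seed(seed, rca_modules(dim(x)[4], bins))
  }
  apply_block(module, input)
}
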