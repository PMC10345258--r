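## Full GC-UNet assembly: densely connected encoder, context-aware gate
## pooling bottleneck, decoder stages with residual context attention, and
## the training loss.

densenet_presets <- list(
  ## the canonical 121-layer configuration
  densenet121 = list(growth = 32L, layers = c(6L, 12L, 24L, 16L),
                     init_channels = 64L, bn_size = 4L),
  ## a reduced variant with the same connectivity pattern, sized so the
  ## network trains in minutes on a single CPU core
  densenet_lite = list(growth = 32L, layers = c(2L, 4L, 6L, 4L),
                       init_channels = 64L, bn_size = 4L)
)

dense_layer_module <- function(ctx, name, cin, growth, bn_size) {
  bn1 <- nn_bn(ctx, paste0(name, ".bn1"), cin)
  conv1 <- nn_conv(ctx, paste0(name, ".conv1"), cin, bn_size * growth, 1L)
  bn2 <- nn_bn(ctx, paste0(name, ".bn2"), bn_size * growth)
  conv2 <- nn_conv(ctx, paste0(name, ".conv2"), bn_size * growth, growth, 3L)
  function(x, training) {
    h <- conv1$fwd(op_relu(bn1$fwd(x, training)))
    h <- conv2$fwd(op_relu(bn2$fwd(h, training)))
    op_concat_c(list(x, h))
  }
}

densenet_encoder <- function(ctx, name, preset) {
  g <- preset$growth
  stem_conv <- nn_conv(ctx, paste0(name, ".stem.conv"), 3L,
                       preset$init_channels, 7L, stride = 2L, pad = 3L)
  stem_bn <- nn_bn(ctx, paste0(name, ".stem.bn"), preset$init_channels)
  ch <- preset$init_channels
  skip_channels <- integer(4)
  skip_channels[1] <- ch
  blocks <- list()
  transitions <- list()
  for (b in seq_len(4)) {
    layers <- list()
    for (l in seq_len(preset$layers[b])) {
      layers[[l]] <- dense_layer_module(
        ctx, sprintf("%s.block%d.layer%d", name, b, l), ch, g, preset$bn_size)
      ch <- ch + g
    }
    blocks[[b]] <- layers
    if (b < 4) {
      skip_channels[b + 1] <- ch
      cout <- ch %/% 2L
      bn <- nn_bn(ctx, sprintf("%s.trans%d.bn", name, b), ch)
      conv <- nn_conv(ctx, sprintf("%s.trans%d.conv", name, b), ch, cout, 1L)
      transitions[[b]] <- list(bn = bn, conv = conv)
      ch <- cout
    }
  }
  final_bn <- nn_bn(ctx, paste0(name, ".final.bn"), ch)
  deep_channels <- ch
  forward <- function(x, training) {
    s1 <- op_relu(stem_bn$fwd(stem_conv$fwd(x), training))       # H/2
    h <- op_maxpool(s1, 3L, stride = 2L, pad = 1L)               # H/4
    skips <- vector("list", 4)
    skips[[1]] <- s1
    for (b in seq_len(4)) {
      for (l in blocks[[b]]) h <- l(h, training)
      if (b < 4) {
        skips[[b + 1]] <- h
        tr <- transitions[[b]]
        h <- tr$conv$fwd(op_relu(tr$bn$fwd(h, training)))
        d <- dims4(h$value)
        h <- op_adaptive_avgpool(h, d[1] %/% 2L, d[2] %/% 2L)    # /2
      }
    }
    h <- op_relu(final_bn$fwd(h, training))                      # H/32
    list(skips = skips, deep = h)
  }
  list(forward = forward, skip_channels = skip_channels,
       deep_channels = deep_channels)
}

#' Model configuration
#'
#' @param encoder_name `"densenet_lite"` (default; same dense connectivity,
#'   sized for CPU training) or `"densenet121"` (the canonical 121-layer
#'   configuration).
#' @param pretrained logical; `TRUE` requests published classification
#'   weights, which are unavailable offline and raise an error. Keep `FALSE`
#'   (random initialization) for fully offline use.
#' @param decoder_widths channel widths of the four decoder stages, deepest
#'   first.
#' @param blocks named list of overrides passed to [block_config()]
#'   (e.g. `list(gca_bottleneck_ratio = 8)`); `channels` is derived from the
#'   encoder and cannot be overridden.
#' @param seed integer seed for parameter initialization.
#' @return list of class `gcu_model_config`.
#' @export
model_config <- function(encoder_name = c("densenet_lite", "densenet121"),
                         pretrained = FALSE,
                         decoder_widths = c(128L, 64L, 32L, 16L),
                         blocks = list(),
                         seed = 0L) {
  encoder_name <- match.arg(encoder_name)
  stopifnot(length(decoder_widths) == 4L, all(decoder_widths >= 1))
  structure(list(encoder_name = encoder_name,
                 pretrained = isTRUE(pretrained),
                 decoder_widths = as.integer(decoder_widths),
                 blocks = blocks,
                 seed = as.integer(seed)),
            class = "gcu_model_config")
}

#' Build a GC-UNet model
#'
#' Assembles the densely connected encoder (5 downsamplings, 4 skip taps),
#' the context-aware gate pooling bottleneck on the deepest map, four
#' decoder stages (each a learned-upsampling stage followed by a residual
#' context attention module) and a final x2 bilinear + 1x1 convolution head
#' producing one logit per pixel.
#'
#' @param config a [model_config()].
#' @return object of class `gcu_model`.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "gcu_model_config"))
  preset <- densenet_presets[[config$encoder_name]]
  if (is.null(preset)) stop("unknown encoder: ", config$encoder_name)
  if (config$pretrained) {
    stop("pretrained weights are not available in this offline build; ",
         "use model_config(pretrained = FALSE) for random initialization",
         call. = FALSE)
  }
  with_seed(config$seed, {
    ctx <- new_ctx()
    enc <- densenet_encoder(ctx, "encoder", preset)
    bargs <- config$blocks
    bargs$channels <- enc$deep_channels
    if (is.null(bargs$fusion_channels)) {
      bargs$fusion_channels <- config$decoder_widths[1]
    }
    bcfg <- do.call(block_config, bargs)
    cagp <- cagp_modules(bcfg, ctx, "cagp")
    widths <- config$decoder_widths
    stages <- list()
    rcas <- list()
    cin <- bcfg$fusion_channels
    for (i in seq_len(4)) {
      cskip <- enc$skip_channels[5 - i]
      stages[[i]] <- decoder_stage_module(
        ctx, sprintf("decoder%d", i), cin, cskip, widths[i])
      rcas[[i]] <- rca_modules(widths[i], bcfg$rca_bins, ctx,
                               sprintf("rca%d", i))
      cin <- widths[i]
    }
    head_conv <- nn_conv(ctx, "head.conv", widths[4], 1L, 1L)
    forward_logits <- function(x, training = FALSE) {
      d <- dims4(x$value)
      e <- enc$forward(x, training)
      h <- cagp$forward(e$deep, training)
      for (i in seq_len(4)) {
        h <- stages[[i]]$forward(h, e$skips[[5 - i]], training)
        h <- rcas[[i]]$forward(h, training, clamp = TRUE)
      }
      head_conv$fwd(op_bilinear(h, d[1], d[2]))
    }
    model <- list(ctx = ctx, config = config, block_config = bcfg,
                  forward_logits = forward_logits,
                  adam = new.env(parent = emptyenv()))
    class(model) <- "gcu_model"
    model
  })
}

#' @export
print.gcu_model <- function(x, ...) {
  cat(sprintf("GC-UNet (%s encoder, decoder widths %s): %d parameters\n",
              x$config$encoder_name,
              paste(x$config$decoder_widths, collapse = "/"),
              n_params(x)))
  invisible(x)
}

check_input_dims <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L) {
    stop(sprintf(
      "input %dx%d: spatial dims must be divisible by 32 (5 downsamplings); pad to a multiple of 32 (see predict_dir, which reflect-pads automatically)",
      h, w), call. = FALSE)
  }
}

#' Run the network on an image
#'
#' @param model a [build_model()] result.
#' @param image H x W x 3 array in \[0,1\] (or H x W x N x 3 batch); H and W
#'   must be divisible by 32.
#' @return probability map: H x W matrix in \[0,1\] (or H x W x N array for
#'   a batch).
#' @export
forward <- function(model, image) {
  stopifnot(inherits(model, "gcu_model"))
  x <- to_batch(image)
  squeeze <- isTRUE(attr(x, "gcu_squeeze"))
  d <- dim(x)
  check_input_dims(d[1], d[2])
  z <- ag_no_grad(model$forward_logits(as_node(drop_marker(x)),
                                       training = FALSE))
  p <- 1 / (1 + exp(-z$value))
  dim(p) <- d[c(1, 2, 3)]
  if (squeeze) dim(p) <- d[c(1, 2)]
  p
}

#' Combined binary cross-entropy + Dice segmentation loss
#'
#' `loss = bce_weight * BCE(pred, target) +
#'  dice_weight * (1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps))`
#' with smoothing `eps = 1` on the sum scale. BCE is averaged over pixels;
#' the Dice term is computed over the whole tensor (batch-global).
#'
#' @param pred probability array in \[0,1\].
#' @param target binary array of the same shape.
#' @param bce_weight,dice_weight nonnegative term weights (default 1, 1).
#' @param eps Dice smoothing constant.
#' @return nonnegative scalar.
#' @export
segmentation_loss <- function(pred, target, bce_weight = 1, dice_weight = 1,
                              eps = 1) {
  if (!identical(dim(pred), dim(target)) &&
      length(pred) != length(target)) {
    stop("pred and target shapes differ", call. = FALSE)
  }
  stopifnot(bce_weight >= 0, dice_weight >= 0)
  p <- pmin(pmax(as.vector(pred), 1e-12), 1 - 1e-12)
  t <- as.vector(target)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  dice <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  bce_weight * bce + dice_weight * dice
}

## Loss value and its gradient with respect to the *logits* (numerically
## stable BCE-with-logits; used by the training loop).
loss_value_grad <- function(z, target, bce_weight = 1, dice_weight = 1,
                            eps = 1) {
  t <- target
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  ## BCE with logits: log(1 + exp(z)) - t*z, computed stably
  bce <- mean(pmax(z, 0) - t * z + log1p(exp(-abs(z))))
  sp <- sum(p)
  st <- sum(t)
  spt <- sum(p * t)
  denom <- sp + st + eps
  dice <- 1 - (2 * spt + eps) / denom
  value <- bce_weight * bce + dice_weight * dice
  gp_dice <- -(2 * t * denom - (2 * spt + eps)) / (denom * denom)
  gz <- bce_weight * (p - t) / n + dice_weight * gp_dice * p * (1 - p)
  dim(gz) <- dim(z)
  list(value = value, grad = gz, bce = bce, dice = dice)
}

## --- checkpoints ------------------------------------------------------------

## 32-bit FNV-1a over the serialized configuration; cheap integrity tag for
## the JSON sidecar.
hash_config <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Save a model checkpoint
#'
#' Writes a binary parameter file plus a human-readable JSON sidecar
#' (`<path>.json`) recording the model configuration and its hash. Loading
#' refuses a checkpoint whose sidecar does not match the requested
#' configuration.
#'
#' @param model a `gcu_model`.
#' @param path checkpoint file path (`.rds`).
#' @param extra named list stored alongside the weights (epoch counter,
#'   optimizer step, RNG state, training records).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  state <- ctx_state(model$ctx)
  obj <- list(state = state, adam_t = model$adam$t,
              config = model$config, extra = extra)
  saveRDS(obj, path, compress = FALSE)  # checkpoints are large and transient
  side <- list(config = unclass(model$config),
               config_hash = hash_config(model$config),
               n_params = n_params(model),
               saved = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @param model optional existing `gcu_model` to load into; built from the
#'   stored configuration when NULL.
#' @return list with `model` and `extra` (as passed to [save_checkpoint()]).
#' @export
load_checkpoint <- function(path, model = NULL) {
  obj <- readRDS(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar)
    if (!identical(side$config_hash, hash_config(obj$config))) {
      stop("checkpoint sidecar config hash mismatch for ", path, call. = FALSE)
    }
  }
  if (is.null(model)) {
    model <- build_model(obj$config)
  } else if (!identical(hash_config(model$config), hash_config(obj$config))) {
    stop("checkpoint was saved with a different model configuration",
         call. = FALSE)
  }
  ctx_restore(model$ctx, obj$state)
  model$adam$t <- obj$adam_t
  list(model = model, extra = obj$extra)
}
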