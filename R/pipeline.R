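## Data loading, augmentation, the training loop, and batch prediction.

#' Augmentation configuration
#'
#' The geometric transforms are right-angle rotations with a small uniform
#' jitter plus fractional translations; the same sampled transform is
#' applied to image (bilinear) and mask (nearest), so pixelwise
#' correspondence is preserved. `reps` on-the-fly variants per image per
#' epoch stand in for a 10x enlarged offline dataset.
#'
#' @param rotate logical; rotate by a random angle from `angles` plus
#'   uniform jitter in `[-jitter_deg, jitter_deg]`.
#' @param angles base rotation angles in degrees.
#' @param jitter_deg rotation jitter half-range in degrees.
#' @param translate logical; shift by up to `max_shift` of each dimension.
#' @param max_shift maximum translation as a fraction of height/width.
#' @param normalize logical; divide 8-bit-range images (max > 1) by 255.
#' @param reps augmented variants sampled per image per epoch.
#' @return list of class `gcu_augment_config`.
#' @export
augment_config <- function(rotate = TRUE, angles = c(0, 90, 180, 270),
                           jitter_deg = 15, translate = TRUE,
                           max_shift = 0.1, normalize = TRUE, reps = 10L) {
  structure(list(rotate = isTRUE(rotate), angles = angles,
                 jitter_deg = jitter_deg, translate = isTRUE(translate),
                 max_shift = max_shift, normalize = isTRUE(normalize),
                 reps = as.integer(reps)),
            class = "gcu_augment_config")
}

## inverse-mapped affine warp with edge-clamped sampling; theta in radians,
## shifts in output pixels; scales handle resizing
warp_plane <- function(m, out_h, out_w, theta, ty, tx, method) {
  H <- nrow(m); W <- ncol(m)
  yc <- (seq_len(out_h) - (out_h + 1) / 2) * (H / out_h)
  xc <- (seq_len(out_w) - (out_w + 1) / 2) * (W / out_w)
  yg <- matrix(yc, out_h, out_w)
  xg <- matrix(xc, out_h, out_w, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  sy <- ct * yg + st * xg + (H + 1) / 2 - ty
  sx <- -st * yg + ct * xg + (W + 1) / 2 - tx
  sy <- pmin(pmax(sy, 1), H)
  sx <- pmin(pmax(sx, 1), W)
  if (method == "nearest") {
    return(matrix(m[cbind(as.vector(round(sy)), as.vector(round(sx)))],
                  out_h, out_w))
  }
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  ay <- sy - y0; ax <- sx - x0
  v <- (1 - ay) * (1 - ax) * m[cbind(as.vector(y0), as.vector(x0))] +
    ay * (1 - ax) * m[cbind(as.vector(y1), as.vector(x0))] +
    (1 - ay) * ax * m[cbind(as.vector(y0), as.vector(x1))] +
    ay * ax * m[cbind(as.vector(y1), as.vector(x1))]
  matrix(v, out_h, out_w)
}

warp_image <- function(img, out_h, out_w, theta = 0, ty = 0, tx = 0,
                       method = "bilinear") {
  if (length(dim(img)) == 2L) {
    return(warp_plane(img, out_h, out_w, theta, ty, tx, method))
  }
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) {
    out[, , ch] <- warp_plane(img[, , ch], out_h, out_w, theta, ty, tx, method)
  }
  out
}

#' Apply one sampled augmentation to an image/mask pair
#'
#' Samples a geometric transform from the configuration (using the current
#' RNG state, so a fixed seed reproduces the pair exactly) and applies the
#' identical transform to both image and mask; the image is interpolated
#' bilinearly, the mask with nearest-neighbour. The pair is resized to
#' `size` x `size` when given.
#'
#' @param image H x W x 3 array.
#' @param mask H x W binary matrix.
#' @param cfg an [augment_config()].
#' @param size optional output size (square).
#' @return list with `image` and `mask`.
#' @export
augment_pair <- function(image, mask, cfg = augment_config(), size = NULL) {
  stopifnot(identical(dim(image)[1:2], dim(mask)[1:2]))
  if (cfg$normalize && max(image) > 1) image <- image / 255
  out_h <- if (is.null(size)) nrow(mask) else as.integer(size)
  out_w <- if (is.null(size)) ncol(mask) else as.integer(size)
  theta <- 0
  ty <- 0
  tx <- 0
  if (cfg$rotate) {
    base <- cfg$angles[sample.int(length(cfg$angles), 1L)]
    jit <- stats::runif(1, -cfg$jitter_deg, cfg$jitter_deg)
    theta <- (base + jit) * pi / 180
  }
  if (cfg$translate) {
    ty <- stats::runif(1, -cfg$max_shift, cfg$max_shift) * nrow(mask)
    tx <- stats::runif(1, -cfg$max_shift, cfg$max_shift) * ncol(mask)
  }
  if (theta == 0 && ty == 0 && tx == 0 &&
      out_h == nrow(mask) && out_w == ncol(mask)) {
    return(list(image = image, mask = mask * 1))
  }
  list(image = warp_image(image, out_h, out_w, theta, ty, tx, "bilinear"),
       mask = warp_plane(mask * 1, out_h, out_w, theta, ty, tx, "nearest"))
}

#' Load matched image/mask pairs from two directories
#'
#' Filename stems must match between the directories after stripping role
#' prefixes (`image_`/`img_` for images, `inst_`/`mask_`/`label_` for
#' masks), so a synthetic dataset directory can serve as both. Pairs are
#' loaded lazily and cached; instance maps are collapsed to binary masks
#' for training targets.
#'
#' @param images_dir directory with 8-bit RGB TIFF images.
#' @param masks_dir directory with 16-bit instance TIFFs (may equal
#'   `images_dir`).
#' @return object of class `gcu_dataset`: fields `n`, `stems`, and
#'   `get(i)` returning `list(image, instances, mask)`.
#' @export
load_pairs <- function(images_dir, masks_dir) {
  imgs <- list_rasters(images_dir, c("image", "img"))
  msks <- list_rasters(masks_dir, c("inst", "mask", "label"))
  missing_mask <- setdiff(names(imgs), names(msks))
  if (length(missing_mask)) {
    stop("no mask for image stem(s): ", paste(missing_mask, collapse = ", "),
         call. = FALSE)
  }
  stems <- sort(names(imgs))
  cache <- new.env(parent = emptyenv())
  get <- function(i) {
    s <- stems[i]
    hit <- get0(s, envir = cache)
    if (!is.null(hit)) return(hit)
    image <- read_tiff(imgs[[s]])
    inst <- read_tiff(msks[[s]])
    if (!identical(dim(image)[1:2], dim(inst))) {
      stop(sprintf("%s: image %s and mask %s shapes differ", s,
                   paste(dim(image)[1:2], collapse = "x"),
                   paste(dim(inst), collapse = "x")), call. = FALSE)
    }
    val <- list(image = image, instances = inst, mask = (inst > 0L) * 1)
    assign(s, val, envir = cache)
    val
  }
  structure(list(n = length(stems), stems = stems, get = get),
            class = "gcu_dataset")
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 1e-4,
#' batch size 8, 200 epochs, 512 x 512 inputs, equally weighted binary
#' cross-entropy + Dice loss. Desk-scale tests override `image_size` and
#' `epochs`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size images per optimization step.
#' @param epochs passes over the dataset.
#' @param image_size square side the inputs are resized to (must be a
#'   multiple of 32).
#' @param optimizer only `"adam"`.
#' @param bce_weight,dice_weight loss term weights.
#' @param augment an [augment_config()], or NULL to disable augmentation.
#' @param seed master seed for shuffling and augmentation sampling.
#' @param checkpoint_every save a checkpoint every this many epochs
#'   (0 = only at the end, and only if `checkpoint_dir` is set).
#' @param checkpoint_dir directory for checkpoints (NULL = no checkpoints).
#' @param lr_schedule `"constant"` (default; the recipe names only a
#'   starting rate) or `"cosine"` decay to 0 over `epochs`.
#' @param device `"cpu"`; `"gpu"` is not available in this build.
#' @return list of class `gcu_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         epochs = 200L, image_size = 512L,
                         optimizer = "adam", bce_weight = 1, dice_weight = 1,
                         augment = augment_config(), seed = 1L,
                         checkpoint_every = 0L, checkpoint_dir = NULL,
                         lr_schedule = c("constant", "cosine"),
                         device = c("cpu", "gpu")) {
  lr_schedule <- match.arg(lr_schedule)
  device <- match.arg(device)
  if (device == "gpu") {
    stop("this build trains on CPU only; use device = \"cpu\"", call. = FALSE)
  }
  if (optimizer != "adam") stop("unsupported optimizer: ", optimizer)
  if (image_size %% 32L != 0L) {
    stop("image_size must be a multiple of 32", call. = FALSE)
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 image_size = as.integer(image_size),
                 optimizer = optimizer,
                 bce_weight = bce_weight, dice_weight = dice_weight,
                 augment = augment, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir,
                 lr_schedule = lr_schedule, device = device),
            class = "gcu_train_config")
}

foreground_dice <- function(prob, target, threshold = 0.5) {
  dice(target > 0.5, prob > threshold)
}

#' Train a model
#'
#' Runs shuffled mini-batch Adam over the dataset, recording per-epoch mean
#' loss and mean foreground Dice (the "accuracy" proxy of the training
#' curves). Fully seeded: the same configuration, dataset and seed
#' reproduce the records exactly; resuming from a checkpoint restores the
#' optimizer moments, batch-norm statistics and RNG state, so subsequent
#' records match an uninterrupted run.
#'
#' @param model a `gcu_model` (modified in place and returned).
#' @param dataset a `gcu_dataset` from [load_pairs()], or a list of
#'   `list(image, mask)` pairs.
#' @param cfg a [train_config()].
#' @param resume_from optional checkpoint path to resume from.
#' @param quiet suppress per-epoch messages.
#' @return list with `model` and `records` (data.frame: epoch, train_loss,
#'   train_dice, lr, seconds).
#' @export
train <- function(model, dataset, cfg = train_config(), resume_from = NULL,
                  quiet = TRUE) {
  stopifnot(inherits(model, "gcu_model"))
  items <- if (inherits(dataset, "gcu_dataset")) {
    lapply(seq_len(dataset$n), dataset$get)
  } else {
    dataset
  }
  n <- length(items)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  size <- cfg$image_size
  aug <- cfg$augment
  augmenting <- !is.null(aug) && (aug$rotate || aug$translate)
  reps <- if (augmenting) aug$reps else 1L
  records <- NULL
  epoch0 <- 0L
  set.seed(cfg$seed)
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from, model)
    model <- ck$model
    epoch0 <- ck$extra$epoch
    records <- ck$extra$records
    if (!is.null(ck$extra$rng_state)) {
      assign(".Random.seed", ck$extra$rng_state, envir = globalenv())
    }
  }
  prep <- function(item) {
    img <- item$image
    msk <- item$mask
    if (augmenting) {
      return(augment_pair(img, msk, aug, size))
    }
    if (!is.null(aug) && aug$normalize && max(img) > 1) img <- img / 255
    if (nrow(msk) != size || ncol(msk) != size) {
      img <- warp_image(img, size, size)
      msk <- warp_plane(msk * 1, size, size, 0, 0, 0, "nearest")
    }
    list(image = img, mask = msk)
  }
  t0 <- proc.time()[3]
  for (epoch in seq.int(epoch0 + 1L, length.out = cfg$epochs - epoch0)) {
    lr <- switch(cfg$lr_schedule,
                 constant = cfg$learning_rate,
                 cosine = cfg$learning_rate * 0.5 *
                   (1 + cos(pi * (epoch - 1) / cfg$epochs)))
    order <- sample(rep(seq_len(n), reps))
    losses <- c()
    dices <- c()
    bstart <- seq(1, length(order), by = cfg$batch_size)
    for (bi in seq_along(bstart)) {
      ids <- order[seq.int(bstart[bi],
                           min(bstart[bi] + cfg$batch_size - 1L,
                               length(order)))]
      B <- length(ids)
      x <- array(0, c(size, size, B, 3L))
      tg <- array(0, c(size, size, B, 1L))
      for (k in seq_len(B)) {
        pr <- prep(items[[ids[k]]])
        x[, , k, ] <- pr$image
        tg[, , k, 1] <- pr$mask
      }
      ag_zero_grad(model$ctx$params)
      z <- model$forward_logits(ag_node(x), training = TRUE)
      lg <- loss_value_grad(z$value, tg, cfg$bce_weight, cfg$dice_weight)
      if (!is.finite(lg$value)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi),
             call. = FALSE)
      }
      ag_backward(z, lg$grad)
      adam_step(model$ctx$params, model$adam, lr = lr)
      losses <- c(losses, lg$value)
      pb <- k_sigmoid(z$value)
      dim(pb) <- dim(tg)
      dices <- c(dices, foreground_dice(pb, tg))
    }
    rec <- data.frame(epoch = epoch, train_loss = mean(losses),
                      train_dice = mean(dices), lr = lr,
                      seconds = unname(proc.time()[3] - t0))
    records <- rbind(records, rec)
    if (!quiet) {
      message(sprintf("epoch %d: loss %.4f dice %.4f", epoch,
                      rec$train_loss, rec$train_dice))
    }
    ckpt_now <- !is.null(cfg$checkpoint_dir) &&
      ((cfg$checkpoint_every > 0L && epoch %% cfg$checkpoint_every == 0L) ||
         epoch == cfg$epochs)
    if (ckpt_now) {
      dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(
        model, file.path(cfg$checkpoint_dir,
                         sprintf("ckpt_epoch_%04d.rds", epoch)),
        extra = list(epoch = epoch, records = records,
                     rng_state = get(".Random.seed", globalenv())))
    }
  }
  list(model = model, records = records)
}

## reflect-pad an image up to multiples of `mult` (bottom/right)
pad_to_multiple <- function(img, mult = 32L) {
  H <- dim(img)[1]; W <- dim(img)[2]
  ph <- (mult - H %% mult) %% mult
  pw <- (mult - W %% mult) %% mult
  if (ph == 0L && pw == 0L) return(list(img = img, H = H, W = W))
  ridx <- c(seq_len(H), rev(seq_len(H))[seq_len(ph)])
  cidx <- c(seq_len(W), rev(seq_len(W))[seq_len(pw)])
  list(img = img[ridx, cidx, , drop = FALSE], H = H, W = W)
}

#' Predict segmentations for a directory of images
#'
#' Reads every image, reflect-pads it to a multiple of 32, runs the network
#' in evaluation mode, crops back, and writes per image: the probability
#' map (`prob_<stem>.tiff`, 32-bit float), the thresholded binary mask
#' (`mask_<stem>.tiff`, 16-bit, 0/1) and the extracted instance map
#' (`inst_<stem>.tiff`, 16-bit), plus a `manifest.json`.
#'
#' @param model a trained `gcu_model`.
#' @param images_dir input directory (8-bit RGB TIFFs).
#' @param out_dir output directory.
#' @param threshold,min_size instance extraction parameters.
#' @return the manifest, invisibly.
#' @export
predict_dir <- function(model, images_dir, out_dir, threshold = 0.5,
                        min_size = 10L) {
  imgs <- list_rasters(images_dir, c("image", "img"))
  if (length(imgs) == 0L) stop("no images found in ", images_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (s in sort(names(imgs))) {
    img <- read_tiff(imgs[[s]])
    if (max(img) > 1) img <- img / 255
    pd <- pad_to_multiple(img)
    prob <- forward(model, pd$img)
    prob <- prob[seq_len(pd$H), seq_len(pd$W)]
    inst <- extract_instances(prob, threshold, min_size)
    fp <- sprintf("prob_%s.tiff", s)
    fm <- sprintf("mask_%s.tiff", s)
    fi <- sprintf("inst_%s.tiff", s)
    write_tiff(prob, file.path(out_dir, fp), "float32")
    write_tiff(matrix(as.integer(prob > threshold), nrow(prob)),
               file.path(out_dir, fm), "uint16")
    write_tiff(inst, file.path(out_dir, fi), "uint16")
    entries[[s]] <- list(prob = fp, mask = fm, inst = fi,
                         n_instances = max(0L, max(inst)))
  }
  manifest <- list(model = unclass(model$config), threshold = threshold,
                   min_size = min_size, images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
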