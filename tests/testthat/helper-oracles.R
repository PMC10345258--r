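# Independent brute-force reference implementations. These deliberately use
# plain loops over pixel/instance sets and never call the package's
# vectorized code paths, so agreement is evidence, not tautology.

# elementwise context gating: x is H x W x C; W a C x C matrix (rows = input
# channel, cols = output channel), b length C
oracle_context_gate <- function(x, W, b) {
  out <- x * 0
  for (h in seq_len(dim(x)[1])) {
    for (w in seq_len(dim(x)[2])) {
      v <- x[h, w, ]
      z <- numeric(length(b))
      for (co in seq_along(b)) {
        z[co] <- sum(v * W[, co]) + b[co]
      }
      out[h, w, ] <- v / (1 + exp(-z))
    }
  }
  out
}

# spatial-softmax attention pooling: score each position with a 1x1
# convolution (wa length C, scalar ba), softmax over positions, contract
oracle_gca_context <- function(x, wa, ba) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  score <- matrix(0, H, W)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    score[h, w] <- sum(x[h, w, ] * wa) + ba
  }
  e <- exp(score - max(score))
  A <- e / sum(e)
  ct <- numeric(C)
  for (c in seq_len(C)) {
    s <- 0
    for (h in seq_len(H)) for (w in seq_len(W)) s <- s + x[h, w, c] * A[h, w]
    ct[c] <- s
  }
  ct
}

# non-overlapping window max (floor mode), per channel
oracle_window_max <- function(x, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  oh <- H %/% k; ow <- W %/% k
  out <- array(0, c(oh, ow, C))
  for (c in seq_len(C)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    out[i, j, c] <- max(x[(i - 1) * k + seq_len(k),
                          (j - 1) * k + seq_len(k), c])
  }
  out
}

oracle_dice <- function(g, p) {
  g <- which(g > 0); p <- which(p > 0)
  if (length(g) + length(p) == 0) return(1)
  2 * length(intersect(g, p)) / (length(g) + length(p))
}

# set-based AJI: per ground-truth instance (ascending id), best-IoU
# prediction among intersecting not-yet-consumed ones, ties to lowest id
oracle_aji <- function(gt, pred) {
  gids <- sort(setdiff(unique(as.vector(gt)), 0))
  pids <- sort(setdiff(unique(as.vector(pred)), 0))
  if (length(gids) == 0 && length(pids) == 0) return(1)
  gset <- lapply(gids, function(i) which(gt == i))
  pset <- lapply(pids, function(j) which(pred == j))
  used <- rep(FALSE, length(pids))
  num <- 0; den <- 0
  for (i in seq_along(gids)) {
    best_j <- 0; best_iou <- -1
    for (j in seq_along(pids)) {
      if (used[j]) next
      inter <- length(intersect(gset[[i]], pset[[j]]))
      if (inter == 0) next
      iou <- inter / length(union(gset[[i]], pset[[j]]))
      if (iou > best_iou) { best_iou <- iou; best_j <- j }
    }
    if (best_j == 0) {
      den <- den + length(gset[[i]])
    } else {
      inter <- length(intersect(gset[[i]], pset[[best_j]]))
      num <- num + inter
      den <- den + length(union(gset[[i]], pset[[best_j]]))
      used[best_j] <- TRUE
    }
  }
  for (j in seq_along(pids)) if (!used[j]) den <- den + length(pset[[j]])
  num / den
}

oracle_pq <- function(gt, pred) {
  gids <- sort(setdiff(unique(as.vector(gt)), 0))
  pids <- sort(setdiff(unique(as.vector(pred)), 0))
  ious <- c()
  matched_p <- c()
  for (i in gids) {
    gi <- which(gt == i)
    for (j in pids) {
      pj <- which(pred == j)
      iou <- length(intersect(gi, pj)) / length(union(gi, pj))
      if (iou > 0.5) {
        ious <- c(ious, iou)
        matched_p <- c(matched_p, j)
      }
    }
  }
  tp <- length(ious)
  fp <- length(pids) - tp
  fn <- length(gids) - tp
  if (tp + fp + fn == 0) return(list(pq = 1, sq = 1, rq = 1, tp = 0,
                                     fp = 0, fn = 0))
  sq <- if (tp > 0) mean(ious) else 0
  rq <- tp / (tp + fp / 2 + fn / 2)
  list(pq = sq * rq, sq = sq, rq = rq, tp = tp, fp = fp, fn = fn)
}

# random instance map: k axis-aligned blobs, later ids overwrite earlier
random_instance_map <- function(H, W, max_k = 5) {
  m <- matrix(0L, H, W)
  k <- sample.int(max_k + 1L, 1L) - 1L
  for (i in seq_len(k)) {
    h0 <- sample.int(H, 1); w0 <- sample.int(W, 1)
    dh <- sample.int(max(2, H %/% 2), 1); dw <- sample.int(max(2, W %/% 2), 1)
    m[h0:min(H, h0 + dh), w0:min(W, w0 + dw)] <- i
  }
  m
}

rand_fm <- function(H, W, C) array(stats::rnorm(H * W * C), c(H, W, C))

# small 64x64 scene spec used across pipeline/network tests
desk_spec <- function(seed, n = c(3L, 6L)) {
  scene_spec(height = 64, width = 64, n_nuclei = n, radius_px = c(5, 10),
             eccentricity = c(0, 0.6), overlap_fraction = 0.3,
             texture_noise_sd = 0.03, blur_sigma_px = 0.8, seed = seed)
}

# stack gcu_samples into batch arrays
stack_samples <- function(samples) {
  H <- nrow(samples[[1]]$instances); W <- ncol(samples[[1]]$instances)
  B <- length(samples)
  x <- array(0, c(H, W, B, 3)); tg <- array(0, c(H, W, B, 1))
  for (i in seq_len(B)) {
    x[, , i, ] <- samples[[i]]$image
    tg[, , i, 1] <- samples[[i]]$binary
  }
  list(x = x, t = tg)
}

train_dice_of <- function(z, tg) {
  p <- 1 / (1 + exp(-z))
  gcunet::dice(tg > 0.5, p > 0.5)
}
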