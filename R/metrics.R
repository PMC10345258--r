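## Instance-level evaluation: aggregated Jaccard index, Dice coefficient,
## panoptic quality with IoU > 0.5 matching, and extraction of instance
## maps from probability maps. Instance maps are integer H x W matrices,
## 0 = background, ids >= 1 label instances (ids may be sparse).

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  }
}

## sparse contingency of two label maps over pixels where either is nonzero;
## returns a data.frame (gt, pred, n) plus per-id pixel counts
label_overlap <- function(gt, pred) {
  gt <- as.integer(gt)
  pred <- as.integer(pred)
  idx <- which(gt > 0L | pred > 0L)
  gsz <- table(gt[gt > 0L])
  psz <- table(pred[pred > 0L])
  if (length(idx)) {
    key <- paste(gt[idx], pred[idx])
    tab <- table(key)
    parts <- strsplit(names(tab), " ", fixed = TRUE)
    ov <- data.frame(
      gt = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      pred = vapply(parts, function(p) as.integer(p[2]), integer(1)),
      n = as.integer(tab))
  } else {
    ov <- data.frame(gt = integer(0), pred = integer(0), n = integer(0))
  }
  list(overlap = ov,
       gt_ids = as.integer(names(gsz)), gt_sizes = as.integer(gsz),
       pred_ids = as.integer(names(psz)), pred_sizes = as.integer(psz))
}

#' Extract an instance map from a probability map
#'
#' Thresholds the map, labels connected components (4-connectivity by
#' default; 8 available) and removes components smaller than `min_size`
#' pixels. Ids are assigned in raster-scan order (row by row) of each
#' component's first pixel and re-sequenced to 1..K after size filtering.
#'
#' @param prob numeric H x W matrix in \[0,1\].
#' @param threshold binarization threshold in (0,1); foreground is
#'   `prob > threshold`.
#' @param min_size minimum component area in pixels (smaller components are
#'   dropped; 0 keeps everything).
#' @param connectivity 4 or 8.
#' @return integer H x W instance map.
#' @export
extract_instances <- function(prob, threshold = 0.5, min_size = 10L,
                              connectivity = 4L) {
  stopifnot(is.matrix(prob), threshold > 0, threshold < 1, min_size >= 0,
            connectivity %in% c(4L, 8L))
  fg <- matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
  lab <- k_label_components(fg, as.integer(connectivity))
  if (min_size > 0L) {
    sizes <- tabulate(lab)
    drop <- which(sizes < min_size)
    if (length(drop)) lab[lab %in% drop] <- 0L
  }
  ids <- sort(unique(lab[lab > 0L]))  # ascending = raster order of first pixel
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  lab
}

#' Aggregated Jaccard index
#'
#' For each ground-truth instance (in ascending id order) the best-IoU
#' prediction among those not yet consumed is selected (ties broken by the
#' lowest prediction id); its intersection and union accumulate into the
#' numerator and denominator. Ground-truth instances with no intersecting
#' prediction contribute their own area to the denominator, as does every
#' prediction left unconsumed. Defined as 1 when both maps are empty.
#'
#' @param gt,pred integer instance maps of identical shape.
#' @return scalar in \[0,1\].
#' @export
aji <- function(gt, pred) {
  check_same_shape(gt, pred)
  lo <- label_overlap(gt, pred)
  if (length(lo$gt_ids) == 0L && length(lo$pred_ids) == 0L) return(1)
  gsz <- stats::setNames(lo$gt_sizes, lo$gt_ids)
  psz <- stats::setNames(lo$pred_sizes, lo$pred_ids)
  ov <- lo$overlap[lo$overlap$gt > 0L & lo$overlap$pred > 0L, , drop = FALSE]
  used <- character(0)
  num <- 0
  den <- 0
  for (gi in as.character(sort(lo$gt_ids))) {
    cand <- ov[ov$gt == as.integer(gi), , drop = FALSE]
    if (nrow(cand)) cand <- cand[!(as.character(cand$pred) %in% used), ,
                                 drop = FALSE]
    if (nrow(cand) == 0L) {
      den <- den + gsz[[gi]]
      next
    }
    un <- gsz[[gi]] + psz[as.character(cand$pred)] - cand$n
    iou <- cand$n / un
    best <- which(iou == max(iou))
    best <- best[which.min(cand$pred[best])]  # tie: lowest prediction id
    num <- num + cand$n[best]
    den <- den + un[best]
    used <- c(used, as.character(cand$pred[best]))
  }
  for (pj in as.character(lo$pred_ids)) {
    if (!(pj %in% used)) den <- den + psz[[pj]]
  }
  as.numeric(num / den)
}

#' Dice coefficient of two binary masks
#'
#' `2|G intersect P| / (|G| + |P|)`; defined as 1 when both masks are empty.
#'
#' @param gt_mask,pred_mask logical/0-1 arrays of identical shape.
#' @return scalar in \[0,1\].
#' @export
dice <- function(gt_mask, pred_mask) {
  check_same_shape(gt_mask, pred_mask)
  g <- gt_mask > 0
  p <- pred_mask > 0
  sg <- sum(g)
  sp <- sum(p)
  if (sg + sp == 0L) return(1)
  2 * sum(g & p) / (sg + sp)
}

#' Panoptic quality with IoU > 0.5 matching
#'
#' Pairs with intersection-over-union above 0.5 are matched; above this
#' threshold the matching is provably unique, so no tie-breaking is needed.
#' TP = matched pairs, FP = unmatched predictions, FN = unmatched
#' ground-truth instances. `rq = TP / (TP + FP/2 + FN/2)`, `sq` = mean IoU
#' over matched pairs (0 if none), `pq = sq * rq`. Both maps empty gives
#' pq = sq = rq = 1 with zero counts.
#'
#' @param gt,pred integer instance maps of identical shape.
#' @return list with `pq`, `sq`, `rq`, `tp`, `fp`, `fn` and `pairs`
#'   (data.frame of gt id, pred id, iou).
#' @export
panoptic_quality <- function(gt, pred) {
  check_same_shape(gt, pred)
  lo <- label_overlap(gt, pred)
  ov <- lo$overlap[lo$overlap$gt > 0L & lo$overlap$pred > 0L, , drop = FALSE]
  gsz <- stats::setNames(lo$gt_sizes, lo$gt_ids)
  psz <- stats::setNames(lo$pred_sizes, lo$pred_ids)
  if (nrow(ov)) {
    un <- gsz[as.character(ov$gt)] + psz[as.character(ov$pred)] - ov$n
    iou <- as.numeric(ov$n / un)
    keep <- iou > 0.5
    pairs <- data.frame(gt = ov$gt[keep], pred = ov$pred[keep],
                        iou = iou[keep])
    pairs <- pairs[order(pairs$gt), , drop = FALSE]  # stable report order
  } else {
    pairs <- data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  }
  tp <- nrow(pairs)
  fp <- length(lo$pred_ids) - tp
  fn <- length(lo$gt_ids) - tp
  if (tp + fp + fn == 0L) {
    return(list(pq = 1, sq = 1, rq = 1, tp = 0L, fp = 0L, fn = 0L,
                pairs = pairs))
  }
  sq <- if (tp > 0L) mean(pairs$iou) else 0
  rq <- tp / (tp + fp / 2 + fn / 2)
  list(pq = sq * rq, sq = sq, rq = rq, tp = tp, fp = as.integer(fp),
       fn = as.integer(fn), pairs = pairs)
}

#' Evaluate a probability map against a ground-truth instance map
#'
#' Extracts instances from the probability map, then reports AJI, Dice (on
#' the binarized maps) and panoptic quality in one record.
#'
#' @param gt integer instance map.
#' @param prob numeric probability map of the same shape.
#' @param threshold,min_size,connectivity see [extract_instances()].
#' @return list of class `gcu_metric_report` with fields `aji`, `dice`,
#'   `pq`, `sq`, `rq`, `tp`, `fp`, `fn`, `n_gt`, `n_pred`.
#' @export
evaluate_pair <- function(gt, prob, threshold = 0.5, min_size = 10L,
                          connectivity = 4L) {
  check_same_shape(gt, prob)
  pred <- extract_instances(prob, threshold, min_size, connectivity)
  report_pair(gt, pred)
}

## metrics of an already-instanced prediction
report_pair <- function(gt, pred) {
  pq <- panoptic_quality(gt, pred)
  structure(list(aji = aji(gt, pred), dice = dice(gt > 0L, pred > 0L),
                 pq = pq$pq, sq = pq$sq, rq = pq$rq,
                 tp = pq$tp, fp = pq$fp, fn = pq$fn,
                 n_gt = length(unique(gt[gt > 0L])),
                 n_pred = length(unique(pred[pred > 0L]))),
            class = "gcu_metric_report")
}

#' @export
print.gcu_metric_report <- function(x, ...) {
  cat(sprintf("AJI %.4f  Dice %.4f  PQ %.4f (SQ %.4f RQ %.4f)  TP/FP/FN %d/%d/%d\n",
              x$aji, x$dice, x$pq, x$sq, x$rq, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Evaluate directories of instance maps
#'
#' Matches ground-truth and prediction rasters by filename stem, computes
#' AJI/Dice/PQ per image, and writes a JSON report (per-image rows plus a
#' mean row) and a CSV next to it when `out` is given.
#'
#' @param gt_dir directory of ground-truth 16-bit instance TIFFs.
#' @param pred_dir directory of predicted instance TIFFs.
#' @param out optional path of the JSON report (`.csv` written alongside).
#' @return data.frame of per-image metrics with a final `mean` row.
#' @export
evaluate_dirs <- function(gt_dir, pred_dir, out = NULL) {
  gtf <- list_rasters(gt_dir, c("inst", "mask", "label"))
  prf <- list_rasters(pred_dir, c("inst", "mask", "label"))
  stems <- intersect(names(gtf), names(prf))
  if (length(stems) == 0L) {
    stop("no matching filename stems between ", gt_dir, " and ", pred_dir,
         call. = FALSE)
  }
  missing_pred <- setdiff(names(gtf), names(prf))
  if (length(missing_pred)) {
    warning("no prediction for: ", paste(missing_pred, collapse = ", "))
  }
  rows <- lapply(sort(stems), function(s) {
    gt <- read_tiff(gtf[[s]])
    pr <- read_tiff(prf[[s]])
    check_same_shape(gt, pr)
    r <- report_pair(gt, pr)
    data.frame(image = s, aji = r$aji, dice = r$dice, pq = r$pq,
               sq = r$sq, rq = r$rq, tp = r$tp, fp = r$fp, fn = r$fn)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(image = "mean", aji = mean(df$aji),
                         dice = mean(df$dice), pq = mean(df$pq),
                         sq = mean(df$sq), rq = mean(df$rq),
                         tp = sum(df$tp), fp = sum(df$fp), fn = sum(df$fn))
  df <- rbind(df, mean_row)
  if (!is.null(out)) {
    jsonlite::write_json(df, out, dataframe = "rows", digits = NA,
                         pretty = TRUE)
    utils::write.csv(df, sub("\\.json$", ".csv", out), row.names = FALSE)
  }
  df
}

## Map raster files to stems. When some files carry one of the preferred
## role prefixes (e.g. "inst_") only those are kept and the prefix is
## stripped, so image_0001.tiff and inst_0001.tiff in one directory resolve
## to the same stem without colliding.
list_rasters <- function(dir, prefer = c("image", "img")) {
  files <- list.files(dir, pattern = "\\.(tiff?|TIFF?)$", full.names = TRUE)
  base <- tools::file_path_sans_ext(basename(files))
  pat <- paste0("^(", paste(prefer, collapse = "|"), ")[_-]?")
  hit <- grepl(pat, base)
  if (any(hit)) {
    files <- files[hit]
    base <- sub(pat, "", base[hit])
  }
  stats::setNames(as.list(files), base)
}
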