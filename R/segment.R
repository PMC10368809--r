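## Nucleus detection on DAPI and evaluation of label masks against ground
## truth: IoU-matched object F1 and pixel accuracy.

#' Detect nuclei on a DAPI channel
#'
#' Classical detector: Gaussian smoothing, Otsu threshold, distance-transform
#' watershed to split touching nuclei, then removal of objects below
#' `minAreaPx`. Deterministic.
#'
#' @param dapi Numeric matrix (DAPI intensities).
#' @param smoothSigma Gaussian smoothing sigma, pixels.
#' @param minAreaPx Minimum object area, pixels.
#' @param watershedTolerance Minimum depth between objects in the
#'   distance-transform watershed (see [EBImage::watershed()]).
#' @return Integer label matrix with contiguous ids 1..K (a `LabelMask`).
#' @export
#' @examples
#' img <- matrix(0, 64, 64); img[20:28, 20:28] <- 1
#' max(detectNuclei(img))
detectNuclei <- function(dapi, smoothSigma = 2, minAreaPx = 20L,
                         watershedTolerance = 1) {
  if (!length(dapi)) stop("empty raster")
  rng <- range(dapi)
  if (diff(rng) == 0) {
    warning("constant DAPI raster: returning an empty label mask")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  img <- EBImage::Image((dapi - rng[1]) / diff(rng))
  if (smoothSigma > 0) img <- EBImage::gblur(img, sigma = smoothSigma)
  bw <- img > EBImage::otsu(img, range = c(0, 1))
  dm <- EBImage::distmap(bw)
  ws <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1)
  lab <- as.matrix(EBImage::imageData(ws))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minAreaPx)
  relabelMask(matrix(ifelse(lab %in% keep, lab, 0L), nrow(lab), ncol(lab)))
}

#' Normalize a label mask to contiguous ids
#'
#' @param mask Integer matrix, 0 = background.
#' @return Integer matrix with ids renumbered 1..K preserving order.
#' @export
relabelMask <- function(mask) {
  ids <- sort(unique(mask[mask > 0]))
  out <- matrix(match(mask, ids, nomatch = 0L), nrow(mask), ncol(mask))
  storage.mode(out) <- "integer"
  out
}

#' Intersection over union of two pixel sets
#'
#' @param a,b Logical matrices of identical shape (or masks coercible with
#'   `> 0`).
#' @return IoU in [0, 1]. Both sets empty is undefined and errors.
#' @export
#' @examples
#' a <- matrix(FALSE, 4, 4); b <- a
#' a[1:2, 1:2] <- TRUE; b[2:3, 1:2] <- TRUE
#' iou(a, b)  # 2/6
iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("rasters must have the same shape")
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0) stop("IoU undefined: both pixel sets are empty")
  sum(a & b) / un
}

## Sparse pairwise IoU table between two label masks:
## data.frame(pred, gt, iou) over co-occurring label pairs.
.pairwiseIoU <- function(pred, gt) {
  idx <- which(pred > 0L & gt > 0L)
  areaP <- tabulate(pred[pred > 0L])
  areaG <- tabulate(gt[gt > 0L])
  if (!length(idx))
    return(data.frame(pred = integer(0), gt = integer(0), iou = numeric(0)))
  key <- paste(pred[idx], gt[idx])
  tab <- table(key)
  pg <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  p <- as.integer(pg[, 1]); g <- as.integer(pg[, 2])
  inter <- as.integer(tab)
  data.frame(pred = p, gt = g,
             iou = inter / (areaP[p] + areaG[g] - inter))
}

#' Match predicted to ground-truth objects by IoU
#'
#' Candidate pairs with IoU strictly above `iouThreshold` are matched
#' one-to-one, greedily in descending IoU (ties broken by lower predicted
#' then lower ground-truth id, for determinism). On small scenes this greedy
#' rule attains the optimal matched count (checked against brute force in
#' the test suite).
#'
#' @param pred,gt Integer label masks of identical shape.
#' @param iouThreshold Strict IoU threshold in (0, 1); default 0.6.
#' @return A [SegMatch-class] with matched pairs and TP/FP/FN counts.
#' @export
matchObjects <- function(pred, gt, iouThreshold = 0.6) {
  if (!identical(dim(pred), dim(gt))) stop("masks must have the same shape")
  if (iouThreshold <= 0 || iouThreshold >= 1)
    stop("iouThreshold must be in (0, 1)")
  nPred <- length(unique(pred[pred > 0L]))
  nGt <- length(unique(gt[gt > 0L]))
  cand <- .pairwiseIoU(pred, gt)
  cand <- cand[cand$iou > iouThreshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$pred, cand$gt), , drop = FALSE]
  usedP <- usedG <- integer(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$pred[r] %in% usedP || cand$gt[r] %in% usedG) next
    keep[r] <- TRUE
    usedP <- c(usedP, cand$pred[r]); usedG <- c(usedG, cand$gt[r])
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  tp <- nrow(pairs)
  new("SegMatch", pairs = pairs, tp = as.integer(tp),
      fp = as.integer(nPred - tp), fn = as.integer(nGt - tp),
      iouThreshold = iouThreshold)
}

#' Segmentation metrics from a match result
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2PR / (P + R) (0 when P + R = 0). Pixel accuracy is the fraction of
#' pixels whose binary foreground/background assignment agrees between the
#' two masks.
#'
#' @param match A [SegMatch-class] from [matchObjects()].
#' @param pred,gt The label masks the match was computed from.
#' @return A [SegMetrics-class].
#' @export
computeMetrics <- function(match, pred, gt) {
  tp <- match@tp; fp <- match@fp; fn <- match@fn
  precision <- if (tp + fp == 0) {
    warning("no predicted objects: precision defined as 0"); 0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  pa <- mean((pred > 0L) == (gt > 0L))
  new("SegMetrics", precision = precision, recall = recall, f1 = f1,
      pixelAccuracy = pa)
}

#' Evaluate a segmentation against ground truth
#'
#' Convenience wrapper: [matchObjects()] then [computeMetrics()].
#'
#' @inheritParams matchObjects
#' @return A [SegMetrics-class].
#' @export
evaluateSegmentation <- function(pred, gt, iouThreshold = 0.6) {
  computeMetrics(matchObjects(pred, gt, iouThreshold), pred, gt)
}

#' Summarize segmentation over several images
#'
#' Reports both the per-image mean of each metric and the pooled metric
#' (counts and pixels pooled over images before computing ratios).
#'
#' @param preds,gts Lists of label masks, pairwise comparable.
#' @param iouThreshold Strict IoU threshold.
#' @return data.frame with rows `per_image_mean` and `pooled`.
#' @export
segmentationSummary <- function(preds, gts, iouThreshold = 0.6) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  ms <- mapply(function(p, g) {
    mt <- matchObjects(p, g, iouThreshold)
    met <- computeMetrics(mt, p, g)
    c(tp = mt@tp, fp = mt@fp, fn = mt@fn,
      agree = sum((p > 0L) == (g > 0L)), px = length(p),
      precision = met@precision, recall = met@recall, f1 = met@f1,
      pa = met@pixelAccuracy)
  }, preds, gts)
  tp <- sum(ms["tp", ]); fp <- sum(ms["fp", ]); fn <- sum(ms["fn", ])
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  data.frame(
    row.names = c("per_image_mean", "pooled"),
    precision = c(mean(ms["precision", ]), prec),
    recall = c(mean(ms["recall", ]), rec),
    f1 = c(mean(ms["f1", ]),
           if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0),
    pixel_accuracy = c(mean(ms["pa", ]),
                       sum(ms["agree", ]) / sum(ms["px", ])))
}
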