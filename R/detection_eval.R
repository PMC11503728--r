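# Detection evaluation: mask IoU, greedy confidence-ordered matching, and
# precision / recall / F1.

#' Mask-level intersection over union of two polygons
#'
#' Both polygons are rasterized onto the frame grid (same fill rule as
#' [rasterize_polygon()]) and the IoU is the ratio of the intersection to
#' the union pixel counts.
#'
#' @param a,b Polygons acceptable to [as_polygon()].
#' @param geom A [frame_geometry()] giving the raster extent.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b, geom) {
  stopifnot(inherits(geom, "frame_geometry"))
  W <- as.integer(geom$W); H <- as.integer(geom$H)
  pa <- .interval_pixels(.polygon_row_intervals(a, W, H), W)
  pb <- .interval_pixels(.polygon_row_intervals(b, W, H), W)
  if (!length(pa) && !length(pb))
    stop("IoU undefined: both masks are empty within the frame", call. = FALSE)
  inter <- length(intersect(pa, pb))
  uni <- length(pa) + length(pb) - inter
  inter / uni
}

# Flatten disjoint row intervals to linear pixel indices y * width + x.
.interval_pixels <- function(iv, width) {
  if (!nrow(iv)) return(integer(0))
  cnt <- iv$hi - iv$lo + 1L
  rep(iv$y, cnt) * width + (rep(iv$lo, cnt) + sequence(cnt) - 1L)
}

#' Match predicted to reference contours by IoU
#'
#' Predictions are sorted by descending confidence (ties keep input order)
#' and each is greedily matched to the unmatched reference contour with the
#' highest IoU at or above `iou_threshold`. Unmatched predictions count as
#' false positives, unmatched references as false negatives.
#'
#' @param preds List of predictions, each a list with `polygon` and
#'   `confidence` (missing confidence is treated as 1).
#' @param truths List of reference polygons.
#' @param geom A [frame_geometry()].
#' @param iou_threshold Minimum IoU for a match, in `(0, 1]` (default 0.5).
#' @return List with `TP`, `FP`, `FN` and `pairs`, a data frame of matched
#'   `(pred, truth, iou)` index pairs.
#' @export
match_detections <- function(preds, truths, geom, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  np <- length(preds); nt <- length(truths)
  conf <- vapply(preds, function(p)
    if (is.null(p$confidence) || is.na(p$confidence)) 1 else p$confidence,
    numeric(1))
  ord <- order(-conf)  # stable: ties keep input order
  used <- logical(nt)
  pairs <- data.frame(pred = integer(0), truth = integer(0), iou = numeric(0))
  for (pi in ord) {
    best_iou <- -1; best_t <- NA_integer_
    for (ti in seq_len(nt)) {
      if (used[ti]) next
      iou <- mask_iou(preds[[pi]]$polygon, truths[[ti]], geom)
      if (iou > best_iou) { best_iou <- iou; best_t <- ti }
    }
    if (!is.na(best_t) && best_iou >= iou_threshold) {
      used[best_t] <- TRUE
      pairs <- rbind(pairs, data.frame(pred = pi, truth = best_t, iou = best_iou))
    }
  }
  list(TP = nrow(pairs), FP = np - nrow(pairs), FN = nt - sum(used),
       pairs = pairs)
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)` (the harmonic mean of P and R). Zero-denominator
#' conventions: `P = 0` when `TP + FP = 0`, `R = 0` when `TP + FN = 0`,
#' `F1 = 0` when `P + R = 0`.
#'
#' @param TP,FP,FN Non-negative match counts.
#' @return Named numeric vector `c(P = , R = , F1 = )`.
#' @examples
#' detection_metrics(9, 1, 3)  # P = 0.9, R = 0.75, F1 ~ 0.818
#' @export
detection_metrics <- function(TP, FP, FN) {
  if (TP < 0 || FP < 0 || FN < 0)
    stop("counts must be non-negative", call. = FALSE)
  P <- if (TP + FP == 0) 0 else TP / (TP + FP)
  R <- if (TP + FN == 0) 0 else TP / (TP + FN)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F1 = F1)
}

#' Precision/recall sweep over confidence thresholds
#'
#' Evaluates [match_detections()] at a grid of minimum-confidence cutoffs so
#' a precision-recall curve can be plotted for a detector.
#'
#' @inheritParams match_detections
#' @param thresholds Confidence cutoffs; default the sorted distinct
#'   prediction confidences.
#' @return Data frame with columns `confidence`, `TP`, `FP`, `FN`, `P`, `R`,
#'   `F1`.
#' @export
confidence_sweep <- function(preds, truths, geom, iou_threshold = 0.5,
                             thresholds = NULL) {
  conf <- vapply(preds, function(p)
    if (is.null(p$confidence) || is.na(p$confidence)) 1 else p$confidence,
    numeric(1))
  if (is.null(thresholds)) thresholds <- sort(unique(conf))
  out <- do.call(rbind, lapply(thresholds, function(th) {
    keep <- preds[conf >= th]
    m <- match_detections(keep, truths, geom, iou_threshold)
    met <- detection_metrics(m$TP, m$FP, m$FN)
    data.frame(confidence = th, TP = m$TP, FP = m$FP, FN = m$FN,
               P = met[["P"]], R = met[["R"]], F1 = met[["F1"]])
  }))
  rownames(out) <- NULL
  out
}
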