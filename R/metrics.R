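# Detection evaluation: IoU, greedy score-ordered matching, precision and
# recall, 101-point interpolated average precision, and the mAP50 /
# mAP50-95 suite (thresholds 0.50, 0.55, ..., 0.95).
#
# Detections are data frames with columns image_id, x1, y1, x2, y2, score,
# class_id; ground truths with image_id, x1, y1, x2, y2, class_id.
# Coordinates are 0-based pixels, boxes x1 < x2, y1 < y2.

#' Intersection over union of two boxes
#'
#' Overlap area divided by union area; 0 for disjoint or degenerate
#' (zero-area) boxes; symmetric and invariant to scaling all coordinates.
#'
#' @param a,b boxes as numeric `c(x1, y1, x2, y2)`.
#' @return a number in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  inter <- max(0, min(a[3], b[3]) - max(a[1], b[1])) *
    max(0, min(a[4], b[4]) - max(a[2], b[2]))
  ua <- max(0, a[3] - a[1]) * max(0, a[4] - a[2]) +
    max(0, b[3] - b[1]) * max(0, b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

empty_dets <- function() {
  data.frame(image_id = integer(), x1 = numeric(), y1 = numeric(),
             x2 = numeric(), y2 = numeric(), score = numeric(),
             class_id = integer())
}

# TP flags for one image's single-class detections (already score-ordered
# within the caller's global ordering): greedy, each det takes the unmatched
# gt of highest IoU >= thr.
match_flags <- function(db, gb, thr) {
  nd <- nrow(db)
  tp <- logical(nd)
  if (nd == 0) return(tp)
  ng <- nrow(gb)
  if (ng == 0) return(tp)
  used <- logical(ng)
  gmat <- as.matrix(gb[, c("x1", "y1", "x2", "y2")])
  for (i in seq_len(nd)) {
    ious <- box_iou_one_many(as.numeric(db[i, c("x1", "y1", "x2", "y2")]),
                             gmat)
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= thr) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  tp
}

#' Match detections to ground truths at one IoU threshold
#'
#' Single class, single image set: detections are processed in descending
#' score order; each is matched to the not-yet-matched ground truth of
#' highest IoU at or above the threshold, and each ground truth can be
#' matched at most once.
#'
#' @param dets detections data frame (see module header; `image_id`
#'   optional, assumed one image when absent).
#' @param gts ground-truth data frame.
#' @param iou_threshold matching threshold.
#' @return a `match_result` list: `tp`, `fp`, `fn` counts and `flags`,
#'   per-detection TP logicals in descending score order.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (is.null(dets$image_id)) dets$image_id <- rep(1L, nrow(dets))
  if (is.null(gts$image_id)) gts$image_id <- rep(1L, nrow(gts))
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  flags <- logical(nrow(d))
  for (im in unique(d$image_id)) {
    sel <- d$image_id == im
    flags[sel] <- match_flags(d[sel, , drop = FALSE],
                              gts[gts$image_id == im, , drop = FALSE],
                              iou_threshold)
  }
  tp <- sum(flags)
  structure(list(tp = tp, fp = nrow(d) - tp, fn = nrow(gts) - tp,
                 flags = flags),
            class = "match_result")
}

#' Precision and recall from a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, with the 0/0 cases defined
#' as 0.
#'
#' @param m a [match_detections()] result (or any list with tp, fp, fn).
#' @return named numeric `c(precision =, recall =)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  c(precision = p, recall = r)
}

#' Average precision at one IoU threshold
#'
#' Area under the precision-recall curve using 101-point interpolation:
#' the mean over recall levels 0, 0.01, ..., 1 of the maximum precision at
#' recall at or above each level.  Single class.
#'
#' @param dets detections across the image set.
#' @param gts ground truths; must be non-empty.
#' @param iou_threshold matching threshold.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(gts) == 0)
    stop("average_precision: AP is undefined without ground truths")
  if (nrow(dets) == 0) return(0)
  m <- match_detections(dets, gts, iou_threshold)
  ctp <- cumsum(m$flags)
  cfp <- cumsum(!m$flags)
  rec <- ctp / nrow(gts)
  prec <- ctp / (ctp + cfp)
  ap_101(rec, prec)
}

ap_101 <- function(rec, prec) {
  # monotone envelope of precision, then sample at 101 recall levels
  n <- length(prec)
  env <- rev(cummax(rev(prec)))
  levels <- seq(0, 1, by = 0.01)
  idx <- findInterval(levels, rec, left.open = TRUE) + 1L
  p <- ifelse(idx <= n, env[pmin(idx, n)], 0)
  mean(p)
}

#' Full metrics suite: P, R, per-class AP, mAP50, mAP50-95
#'
#' Computes per-class AP at IoU thresholds `0.5 + 0.05 * (j - 1)` for
#' j = 1..10; mAP50 is the class mean at 0.5, mAP50-95 the class mean of
#' the 10-threshold average.  Classes without ground truths are excluded
#' from the means with a warning.  Reported precision and recall are taken
#' at the confidence that maximizes F1 on the IoU-0.5 PR curve, pooled over
#' classes.
#'
#' @param dets,gts detection and ground-truth data frames.
#' @return a `metrics_report` list.
#' @export
map_suite <- function(dets, gts) {
  if (nrow(gts) == 0) stop("map_suite: empty evaluation set")
  classes <- sort(unique(gts$class_id))
  stray <- setdiff(unique(dets$class_id), classes)
  if (length(stray) > 0)
    warning("map_suite: detections of classes without ground truths ",
            "contribute nothing: ", paste(stray, collapse = ", "))
  thresholds <- 0.5 + 0.05 * (0:9)
  ap <- matrix(0, nrow = length(classes), ncol = length(thresholds),
               dimnames = list(paste0("class_", classes),
                               paste0("iou_", thresholds)))
  for (ci in seq_along(classes)) {
    dc <- dets[dets$class_id == classes[ci], , drop = FALSE]
    gc <- gts[gts$class_id == classes[ci], , drop = FALSE]
    for (ti in seq_along(thresholds))
      ap[ci, ti] <- average_precision(dc, gc, thresholds[ti])
  }
  # operating point: best F1 along the pooled IoU-0.5 PR curve
  dd <- dets[dets$class_id %in% classes, , drop = FALSE]
  if (nrow(dd) > 0) {
    m <- match_detections(dd, gts, 0.5)
    ord <- order(-dd$score, seq_len(nrow(dd)))
    ctp <- cumsum(m$flags)
    cfp <- cumsum(!m$flags)
    rec <- ctp / nrow(gts)
    prec <- ctp / (ctp + cfp)
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    k <- which.max(f1)
    p <- prec[k]
    r <- rec[k]
    conf <- dd$score[ord][k]
  } else {
    p <- 0; r <- 0; conf <- NA_real_
  }
  structure(list(precision = p, recall = r, conf = conf,
                 classes = classes, per_class_ap = ap,
                 map50 = mean(ap[, 1]),
                 map50_95 = mean(rowMeans(ap))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("P=%.3f R=%.3f (conf %.3f)  mAP50=%.3f  mAP50-95=%.3f\n",
              x$precision, x$recall, x$conf, x$map50, x$map50_95))
  invisible(x)
}
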