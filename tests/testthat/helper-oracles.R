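# Independent oracles the fast paths are checked against.  Everything here
# is deliberately naive: nested loops, exhaustive enumeration.

# direct convolution by nested loops; also counts multiply-accumulates
conv_oracle <- function(x, w, stride = 1, groups = 1) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Cout <- dim(w)[1]; Cpg <- dim(w)[2]; K <- dim(w)[3]
  p <- (K - 1) / 2
  Ho <- floor((H + 2 * p - K) / stride) + 1
  Wo <- floor((W + 2 * p - K) / stride) + 1
  y <- array(0, c(Cout, Ho, Wo))
  macs <- 0
  Coutpg <- Cout / groups
  for (co in 1:Cout) {
    g <- ceiling(co / Coutpg)
    for (oh in 1:Ho) for (ow in 1:Wo) {
      acc <- 0
      for (c in 1:Cpg) {
        ci <- (g - 1) * Cpg + c
        for (kh in 1:K) for (kw in 1:K) {
          ih <- (oh - 1) * stride - p + kh
          iw <- (ow - 1) * stride - p + kw
          macs <- macs + 1  # one kernel tap = one multiply-accumulate
          if (ih >= 1 && ih <= H && iw >= 1 && iw <= W)
            acc <- acc + x[ci, ih, iw] * w[co, c, kh, kw]
        }
      }
      y[co, oh, ow] <- acc
    }
  }
  attr(y, "macs") <- macs
  y
}

rand_fmap <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))

# exhaustive greedy NMS: re-derives the kept set from the definition
nms_oracle <- function(dets, thr) {
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(d))) {
    ok <- TRUE
    for (j in kept) {
      if (d$class_id[j] == d$class_id[i] &&
          iou(as.numeric(d[j, c("x1", "y1", "x2", "y2")]),
              as.numeric(d[i, c("x1", "y1", "x2", "y2")])) > thr) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  d[kept, , drop = FALSE]
}

# greedy matcher by explicit loops (single class, multiple images)
match_oracle <- function(dets, gts, thr) {
  if (is.null(dets$image_id)) dets$image_id <- rep(1L, nrow(dets))
  if (is.null(gts$image_id)) gts$image_id <- rep(1L, nrow(gts))
  d <- dets[order(-dets$score, seq_len(nrow(dets))), , drop = FALSE]
  used <- rep(FALSE, nrow(gts))
  flags <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j] || gts$image_id[j] != d$image_id[i]) next
      v <- iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
               as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thr) { flags[i] <- TRUE; used[bj] <- TRUE }
  }
  list(tp = sum(flags), fp = sum(!flags), fn = nrow(gts) - sum(flags),
       flags = flags)
}

# 101-point AP by direct enumeration over recall levels and ranking prefixes
ap_oracle <- function(dets, gts, thr) {
  if (nrow(dets) == 0) return(0)
  m <- match_oracle(dets, gts, thr)
  tp <- cumsum(m$flags)
  fp <- cumsum(!m$flags)
  rec <- tp / nrow(gts)
  prec <- tp / (tp + fp)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    ok <- which(rec >= r)
    total <- total + if (length(ok)) max(prec[ok]) else 0
  }
  total / 101
}

map_oracle <- function(dets, gts) {
  classes <- sort(unique(gts$class_id))
  thrs <- 0.5 + 0.05 * (0:9)
  ap <- sapply(thrs, function(th)
    sapply(classes, function(cl)
      ap_oracle(dets[dets$class_id == cl, , drop = FALSE],
                gts[gts$class_id == cl, , drop = FALSE], th)))
  ap <- matrix(ap, nrow = length(classes))
  list(map50 = mean(ap[, 1]), map50_95 = mean(rowMeans(ap)))
}

# random box helpers (pixel xyxy inside a 0..S canvas)
rand_boxes <- function(n, S = 100, classes = 0L, min_side = 5) {
  x1 <- runif(n, 0, S - min_side)
  y1 <- runif(n, 0, S - min_side)
  w <- runif(n, min_side, S / 2)
  h <- runif(n, min_side, S / 2)
  data.frame(x1 = x1, y1 = y1, x2 = pmin(x1 + w, S), y2 = pmin(y1 + h, S),
             class_id = classes[sample.int(length(classes), n, TRUE)])
}

digest_file <- function(path) unname(tools::md5sum(path))

# tight bbox of warm (fruit-colored) pixels: red clearly dominant
segment_fruit_bbox <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  mask <- r > 1.15 * g & r > 1.15 * b & r > 0.2
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(x1 = min(idx[, 2]) - 1, y1 = min(idx[, 1]) - 1,
    x2 = max(idx[, 2]), y2 = max(idx[, 1]))
}
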