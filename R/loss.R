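# Detection loss: task-aligned assignment of feature-map cells to targets,
# binary cross-entropy on class scores against aligned soft labels,
# complete-IoU loss on decoded boxes, and a distribution (integral
# regression) loss on the regmax bins.  Weights follow the YOLO-family
# defaults: box 7.5, cls 0.5, dfl 1.5.
#
# The assignment is treated as a constant of each step; analytic gradients
# are seeded directly onto the raw head outputs (the CIoU term uses central
# differences of its closed-form value with respect to the four decoded
# side distances), after which the autodiff tape propagates into every
# weight.

sigmoid <- function(z) 1 / (1 + exp(-z))

# stable elementwise binary cross-entropy from logits
bce_logits <- function(z, t) {
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

# complete IoU of one predicted box against one ground-truth box (xyxy)
ciou_val <- function(p, g) {
  iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- iw * ih
  ap <- max(0, p[3] - p[1]) * max(0, p[4] - p[2])
  ag <- max(0, g[3] - g[1]) * max(0, g[4] - g[2])
  u <- ap + ag - inter
  iou <- if (u > 0) inter / u else 0
  cw <- max(p[3], g[3]) - min(p[1], g[1])
  chh <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- cw^2 + chh^2 + 1e-9
  rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
    ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  wg <- g[3] - g[1]; hg <- g[4] - g[2]
  wp <- max(p[3] - p[1], 1e-9); hp <- max(p[4] - p[2], 1e-9)
  v <- 4 / pi^2 * (atan(wg / max(hg, 1e-9)) - atan(wp / hp))^2
  a <- v / (1 - iou + v + 1e-9)
  iou - rho2 / c2 - a * v
}

# gradient of (1 - CIoU) w.r.t. the four side distances (l, t, r, b) of the
# predicted box anchored at (cx, cy), by central differences
ciou_grad_ltrb <- function(ltrb, cx, cy, g, h = 1e-3) {
  grad <- numeric(4)
  for (i in 1:4) {
    dp <- ltrb; dm <- ltrb
    dp[i] <- dp[i] + h; dm[i] <- dm[i] - h
    bp <- c(cx - dp[1], cy - dp[2], cx + dp[3], cy + dp[4])
    bm <- c(cx - dm[1], cy - dm[2], cx + dm[3], cy + dm[4])
    grad[i] <- -(ciou_val(bp, g) - ciou_val(bm, g)) / (2 * h)
  }
  grad
}

# flatten one image of raw predictions into cell-major matrices
flatten_raw <- function(raw, n, strides) {
  regs <- list(); clss <- list(); meta <- list()
  for (li in seq_along(raw)) {
    rv <- ag_value(raw[[li]]$reg)
    cv <- ag_value(raw[[li]]$cls)
    d <- dim(rv)
    h <- d[2]; w <- d[3]
    regs[[li]] <- matrix(rv[, , , n], nrow = d[1])
    clss[[li]] <- matrix(cv[, , , n], nrow = dim(cv)[1])
    q <- seq_len(h * w) - 1L
    meta[[li]] <- data.frame(
      level = li, h = h, w = w, stride = strides[li],
      cx = ((q %/% h) + 0.5) * strides[li],
      cy = ((q %% h) + 0.5) * strides[li])
  }
  list(reg = do.call(cbind, regs), cls = do.call(cbind, clss),
       anchors = do.call(rbind, meta))
}

#' Detection loss on a batch of raw predictions
#'
#' @param raw model output: list of 3 levels, each `list(reg =, cls =)`
#'   (autodiff nodes or plain arrays with a batch axis).
#' @param targets list with one data frame per image: columns x1, y1, x2,
#'   y2 (pixels), class_id (0-based).  Empty frames are allowed.
#' @param imgsz image side length in pixels.
#' @param regmax number of distance bins per side.
#' @param strides level strides.
#' @param loss_weights weights of the box / cls / dfl terms.
#' @param topk task-aligned assigner candidates per target.
#' @param alpha,beta exponents of the alignment metric
#'   `score^alpha * IoU^beta`.
#' @param backprop seed gradients onto `raw` (requires autodiff nodes).
#' @param assignments optional frozen cell-to-target assignment (as returned
#'   in the `assignments` field of a previous call on the same batch); when
#'   given, the task-aligned assigner is skipped.  The soft targets are
#'   always treated as constants of the step, so a frozen assignment makes
#'   the loss an exactly differentiable function of the raw maps.
#' @return a `loss_breakdown` list: box, cls, dfl, total (all finite,
#'   non-negative), n_assigned, and the per-image `assignments`.
#' @export
detection_loss <- function(raw, targets, imgsz, regmax = 16L,
                           strides = c(8L, 16L, 32L),
                           loss_weights = c(box = 7.5, cls = 0.5, dfl = 1.5),
                           topk = 10L, alpha = 0.5, beta = 6.0,
                           backprop = TRUE, assignments = NULL) {
  N <- length(targets)
  R <- regmax
  bins <- 0:(R - 1)
  tot <- c(box = 0, cls = 0, dfl = 0)
  n_assigned_all <- 0L
  assign_out <- vector("list", N)
  greg_acc <- NULL
  gcls_acc <- NULL
  if (backprop) {
    greg_acc <- lapply(raw, function(l) array(0, dim = dim(ag_value(l$reg))))
    gcls_acc <- lapply(raw, function(l) array(0, dim = dim(ag_value(l$cls))))
  }

  for (n in seq_len(N)) {
    fl <- flatten_raw(raw, n, strides)
    A <- nrow(fl$anchors)
    nc <- nrow(fl$cls)
    p <- sigmoid(fl$cls)                      # nc x A
    # per-side softmax over bins and expected distances (pixels)
    P <- vector("list", 4)
    E <- matrix(0, nrow = A, ncol = 4)
    for (side in 1:4) {
      z <- t(fl$reg[(side - 1) * R + seq_len(R), , drop = FALSE])  # A x R
      Ps <- softmax_rows(z)
      P[[side]] <- Ps
      E[, side] <- as.vector(Ps %*% bins) * fl$anchors$stride
    }
    pb <- cbind(fl$anchors$cx - E[, 1], fl$anchors$cy - E[, 2],
                fl$anchors$cx + E[, 3], fl$anchors$cy + E[, 4])

    gt <- targets[[n]]
    tmat <- matrix(0, nrow = nc, ncol = A)    # soft class targets
    assigned <- integer(0)                    # cell indices
    agt <- integer(0)                         # their target row
    aweight <- numeric(0)
    if (!is.null(assignments)) {
      az <- assignments[[n]]
      tmat <- az$tmat
      assigned <- az$assigned
      agt <- az$agt
      aweight <- az$aweight
    } else if (!is.null(gt) && nrow(gt) > 0) {
      ng <- nrow(gt)
      align <- matrix(0, nrow = ng, ncol = A)
      ioum <- matrix(0, nrow = ng, ncol = A)
      for (g in seq_len(ng)) {
        inb <- fl$anchors$cx > gt$x1[g] & fl$anchors$cx < gt$x2[g] &
          fl$anchors$cy > gt$y1[g] & fl$anchors$cy < gt$y2[g]
        cand <- which(inb)
        if (length(cand) == 0) next
        ious <- box_iou_one_many(as.numeric(gt[g, c("x1", "y1", "x2", "y2")]),
                                 pb[cand, , drop = FALSE])
        sc <- p[gt$class_id[g] + 1L, cand]
        al <- sc^alpha * ious^beta
        ioum[g, cand] <- ious
        k <- min(topk, length(cand))
        top <- cand[order(-al, cand)[seq_len(k)]]
        align[g, top] <- sc[match(top, cand)]^alpha *
          ious[match(top, cand)]^beta
      }
      # resolve conflicts: a cell belongs to the target of max alignment
      cell_best <- apply(align, 2, which.max)
      cell_alig <- align[cbind(cell_best, seq_len(A))]
      sel <- which(cell_alig > 0)
      if (length(sel) > 0) {
        assigned <- sel
        agt <- cell_best[sel]
        for (g in unique(agt)) {
          cells_g <- assigned[agt == g]
          amax <- max(align[g, cells_g])
          imax <- max(ioum[g, cells_g])
          tval <- align[g, cells_g] / (amax + 1e-9) * imax
          tmat[gt$class_id[g] + 1L, cells_g] <- tval
        }
        aweight <- tmat[cbind(gt$class_id[agt] + 1L, assigned)]
      }
    }
    norm <- max(sum(tmat), 1)

    # classification: BCE against the soft targets, everywhere
    cls_l <- sum(bce_logits(fl$cls, tmat)) / norm
    gcls <- (p - tmat) / norm * loss_weights["cls"]

    box_l <- 0
    dfl_l <- 0
    greg <- matrix(0, nrow = 4 * R, ncol = A)
    if (length(assigned) > 0) {
      for (j in seq_along(assigned)) {
        a <- assigned[j]
        g <- agt[j]
        wgt <- aweight[j]
        s <- fl$anchors$stride[a]
        gbox <- as.numeric(gt[g, c("x1", "y1", "x2", "y2")])
        ltrb <- E[a, ]
        cv <- ciou_val(pb[a, ], gbox)
        box_l <- box_l + wgt * (1 - cv)
        # target distances in bin units, clamped into the bin range
        td <- c(fl$anchors$cx[a] - gbox[1], fl$anchors$cy[a] - gbox[2],
                gbox[3] - fl$anchors$cx[a], gbox[4] - fl$anchors$cy[a]) / s
        td <- clamp(td, 0, R - 1 - 1e-3)
        lo <- floor(td); hi <- lo + 1; wl <- hi - td; wh <- td - lo
        if (backprop) gct <- ciou_grad_ltrb(ltrb, fl$anchors$cx[a],
                                            fl$anchors$cy[a], gbox)
        for (side in 1:4) {
          pr <- P[[side]][a, ]
          # distribution loss: CE split across the two adjacent bins
          dfl_l <- dfl_l + wgt *
            (-wl[side] * log(pr[lo[side] + 1] + 1e-12)
             - wh[side] * log(pr[min(hi[side], R - 1) + 1] + 1e-12))
          if (backprop) {
            rows <- (side - 1) * R + seq_len(R)
            tgt <- numeric(R)
            tgt[lo[side] + 1] <- tgt[lo[side] + 1] + wl[side]
            tgt[min(hi[side], R - 1) + 1] <-
              tgt[min(hi[side], R - 1) + 1] + wh[side]
            gdfl <- (pr - tgt) * wgt / (norm * 4) * loss_weights["dfl"]
            # CIoU chain rule through the softmax expectation
            ebin <- sum(pr * bins)
            gbox_z <- gct[side] * s * pr * (bins - ebin) *
              wgt / norm * loss_weights["box"]
            greg[rows, a] <- greg[rows, a] + gdfl + gbox_z
          }
        }
      }
      box_l <- box_l / norm
      dfl_l <- dfl_l / (norm * 4)
    }

    tot <- tot + c(box = box_l, cls = cls_l, dfl = dfl_l) / N
    n_assigned_all <- n_assigned_all + length(assigned)
    assign_out[[n]] <- list(tmat = tmat, assigned = assigned, agt = agt,
                            aweight = aweight)

    if (backprop) {
      at <- 0L
      for (li in seq_along(raw)) {
        cells <- fl$anchors$h[fl$anchors$level == li][1] *
          fl$anchors$w[fl$anchors$level == li][1]
        idx <- at + seq_len(cells)
        dreg <- dim(greg_acc[[li]])
        greg_acc[[li]][, , , n] <- array(greg[, idx], dreg[1:3]) / N
        dcls <- dim(gcls_acc[[li]])
        gcls_acc[[li]][, , , n] <- array(gcls[, idx, drop = FALSE],
                                         dcls[1:3]) / N
        at <- at + cells
      }
    }
  }

  if (backprop) {
    for (li in seq_along(raw)) {
      ag_accum(raw[[li]]$reg, greg_acc[[li]])
      ag_accum(raw[[li]]$cls, gcls_acc[[li]])
    }
  }

  w <- loss_weights
  total <- w["box"] * tot["box"] + w["cls"] * tot["cls"] + w["dfl"] * tot["dfl"]
  structure(list(box = unname(tot["box"]), cls = unname(tot["cls"]),
                 dfl = unname(tot["dfl"]), total = unname(total),
                 weights = w, n_assigned = n_assigned_all,
                 assignments = assign_out),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss %.4f (box %.4f, cls %.4f, dfl %.4f; %d assigned)\n",
              x$total, x$box, x$cls, x$dfl, x$n_assigned))
  invisible(x)
}
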