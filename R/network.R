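# Detector assembly: backbone (inverted bottleneck residual stages), neck
# (bidirectional feature pyramid with normalized fusion weights and ghost
# convolutions on the projections), and an anchor-free decoupled head with
# distribution-style box regression (4 x regmax channels per level).

#' Model configuration
#'
#' @param num_classes number of object classes.
#' @param width_mult channel width multiplier applied to `stage_channels`.
#' @param stage_channels base channel counts of the four backbone stages.
#' @param stage_blocks number of inverted bottleneck blocks per stage.
#' @param expansion channel expansion factor e, scalar or one per stage.
#' @param bifpn_channels pyramid width (not scaled by `width_mult`).
#' @param bifpn_repeats number of bidirectional fusion rounds.
#' @param regmax number of discrete distance bins per box side; the
#'   regression map carries `4 * regmax` channels.
#' @param strides detection strides, strictly increasing powers of two.
#' @return a validated `model_config` list.
#' @export
model_config <- function(num_classes = 1L, width_mult = 0.5,
                         stage_channels = c(64L, 128L, 256L, 512L),
                         stage_blocks = c(1L, 2L, 2L, 1L),
                         expansion = 4,
                         bifpn_channels = 64L, bifpn_repeats = 2L,
                         regmax = 16L, strides = c(8L, 16L, 32L)) {
  bad <- function(msg) stop("model_config: ", msg, call. = FALSE)
  if (num_classes < 1) bad("num_classes must be >= 1")
  if (width_mult <= 0) bad("width_mult must be positive")
  if (length(stage_channels) != 4 || any(stage_channels < 1))
    bad("stage_channels must be 4 positive counts")
  if (length(stage_blocks) != 4 || any(stage_blocks < 1))
    bad("stage_blocks must be 4 positive counts")
  if (length(expansion) == 1) expansion <- rep(expansion, 4)
  if (length(expansion) != 4 || any(expansion <= 0))
    bad("expansion must be positive (scalar or one per stage)")
  if (bifpn_channels < 2 || bifpn_channels %% 2 != 0)
    bad("bifpn_channels must be a positive even count")
  if (bifpn_repeats < 1) bad("bifpn_repeats must be >= 1")
  if (regmax < 2) bad("regmax must be >= 2")
  if (length(strides) != 3 || any(diff(strides) <= 0) ||
      any(log2(strides) != round(log2(strides))))
    bad("strides must be 3 strictly increasing powers of 2")
  structure(list(num_classes = as.integer(num_classes),
                 width_mult = width_mult,
                 stage_channels = as.integer(stage_channels),
                 stage_blocks = as.integer(stage_blocks),
                 expansion = expansion,
                 bifpn_channels = as.integer(bifpn_channels),
                 bifpn_repeats = as.integer(bifpn_repeats),
                 regmax = as.integer(regmax),
                 strides = as.integer(strides)),
            class = "model_config")
}

scaled_ch <- function(base, width_mult) {
  pmax(4L, as.integer(round(base * width_mult)))
}

#' Read a model configuration from a YAML file
#'
#' Recognized keys match the arguments of [model_config()]; missing keys
#' take the defaults.
#' @param path YAML file path.
#' @return a `model_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  keys <- intersect(names(y), names(formals(model_config)))
  do.call(model_config, y[keys])
}

# one normalized-fusion + depthwise-separable-conv node of the pyramid
od_fuse_node <- function(n_inputs, channels, stride = 1L, name = "fuse") {
  m <- new_module("fuse")
  m$params$w <- ag_param(rep(1, n_inputs))
  m$sub$conv <- od_dws(channels, channels, 3L, stride = 1L,
                       name = paste0(name, ".conv"))
  m$forward <- function(xs, training = FALSE) {
    f <- ag_wfuse(xs, m$params$w)
    m$sub$conv$forward(f, training)
  }
  m$complexity <- function(hw) {
    cc <- m$sub$conv$complexity(hw)
    cc$df <- rbind(cx_entry(paste0(name, ".w"), n_inputs, 0), cc$df)
    cc
  }
  m
}

#' Build the detector
#'
#' Stem of two standard 3x3 stride-2 convolutions, four inverted bottleneck
#' stages (strides 1, 2, 2, 2) whose last three outputs form C3/C4/C5 at
#' strides 8/16/32, a bidirectional feature pyramid neck with ghost-conv
#' lateral and output projections, and a per-level decoupled head: standard
#' 3x3 convolutions on the regression branch (4 x regmax channels),
#' depthwise-separable convolutions on the classification branch
#' (`num_classes` channels).
#'
#' @param cfg a [model_config()].
#' @param seed optional integer; when given, weight initialization is
#'   reproducible (two builds with the same seed are identical).
#' @return an `od_model` environment with `$forward`, `$complexity`,
#'   `$cfg`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  if (!inherits(cfg, "model_config")) cfg <- do.call(model_config, cfg)
  if (!is.null(seed)) set.seed(seed)
  ch <- scaled_ch(cfg$stage_channels, cfg$width_mult)
  s0 <- pmax(4L, ch[1] %/% 2L)
  W <- cfg$bifpn_channels
  R <- cfg$regmax
  nc <- cfg$num_classes

  m <- new_module("od_model")
  m$cfg <- cfg
  m$sub$stem <- od_sequential(list(
    od_conv_bn(3L, s0, 3L, 2L, name = "stem1"),
    od_conv_bn(s0, ch[1], 3L, 2L, name = "stem2")), name = "stem")
  st <- c(1L, 2L, 2L, 2L)
  cin <- ch[1]
  for (i in 1:4) {
    m$sub[[paste0("stage", i)]] <-
      od_invres_layer(cin, ch[i], cfg$stage_blocks[i], cfg$expansion[i],
                      3L, st[i], name = paste0("stage", i))
    cin <- ch[i]
  }
  # lateral ghost projections C3/C4/C5 -> pyramid width
  for (i in 1:3)
    m$sub[[paste0("lat", i)]] <-
      od_ghost(ch[i + 1], W, 1L, name = paste0("lat", i))
  # fusion nodes, one set per repeat:
  #   td4 = f(P4, up(P5)); td3 = f(P3, up(td4))
  #   bu4 = f(P4, td4, down(td3)); bu5 = f(P5, down(bu4))
  for (r in seq_len(cfg$bifpn_repeats)) {
    p <- paste0("fpn", r)
    m$sub[[paste0(p, ".td4")]] <- od_fuse_node(2L, W, name = paste0(p, ".td4"))
    m$sub[[paste0(p, ".td3")]] <- od_fuse_node(2L, W, name = paste0(p, ".td3"))
    m$sub[[paste0(p, ".bu4")]] <- od_fuse_node(3L, W, name = paste0(p, ".bu4"))
    m$sub[[paste0(p, ".bu5")]] <- od_fuse_node(2L, W, name = paste0(p, ".bu5"))
    m$sub[[paste0(p, ".down3")]] <- od_dws(W, W, 3L, 2L,
                                           name = paste0(p, ".down3"))
    m$sub[[paste0(p, ".down4")]] <- od_dws(W, W, 3L, 2L,
                                           name = paste0(p, ".down4"))
  }
  for (i in 1:3)
    m$sub[[paste0("out", i)]] <- od_ghost(W, W, 1L, name = paste0("out", i))
  # decoupled head, per-level weights
  for (i in 1:3) {
    m$sub[[paste0("reg", i)]] <- od_sequential(list(
      od_conv_bn(W, W, 3L, name = paste0("reg", i, ".c1")),
      od_conv_bn(W, W, 3L, name = paste0("reg", i, ".c2")),
      od_conv(W, 4L * R, 1L, bias = TRUE, name = paste0("reg", i, ".out"))),
      name = paste0("reg", i))
    cls_out <- od_conv(W, nc, 1L, bias = TRUE, name = paste0("cls", i, ".out"))
    # prior so an untrained model predicts background nearly everywhere
    cls_out$params$b$value[] <- -log((1 - 0.01) / 0.01)
    m$sub[[paste0("cls", i)]] <- od_sequential(list(
      od_dws(W, W, 3L, name = paste0("cls", i, ".c1")),
      od_dws(W, W, 3L, name = paste0("cls", i, ".c2")),
      cls_out), name = paste0("cls", i))
  }

  m$forward <- function(x, training = FALSE) {
    x <- m$sub$stem$forward(x, training)
    feats <- vector("list", 4)
    for (i in 1:4) {
      x <- m$sub[[paste0("stage", i)]]$forward(x, training)
      feats[[i]] <- x
    }
    P <- lapply(1:3, function(i)
      m$sub[[paste0("lat", i)]]$forward(feats[[i + 1]], training))
    for (r in seq_len(m$cfg$bifpn_repeats)) {
      p <- paste0("fpn", r)
      td4 <- m$sub[[paste0(p, ".td4")]]$forward(
        list(P[[2]], ag_upsample2(P[[3]])), training)
      td3 <- m$sub[[paste0(p, ".td3")]]$forward(
        list(P[[1]], ag_upsample2(td4)), training)
      d3 <- m$sub[[paste0(p, ".down3")]]$forward(td3, training)
      bu4 <- m$sub[[paste0(p, ".bu4")]]$forward(
        list(P[[2]], td4, d3), training)
      d4 <- m$sub[[paste0(p, ".down4")]]$forward(bu4, training)
      bu5 <- m$sub[[paste0(p, ".bu5")]]$forward(list(P[[3]], d4), training)
      P <- list(td3, bu4, bu5)
    }
    P <- lapply(1:3, function(i)
      m$sub[[paste0("out", i)]]$forward(P[[i]], training))
    lapply(1:3, function(i) list(
      reg = m$sub[[paste0("reg", i)]]$forward(P[[i]], training),
      cls = m$sub[[paste0("cls", i)]]$forward(P[[i]], training)))
  }

  m$complexity <- function(hw) {
    dfs <- list()
    add <- function(cc) {
      dfs[[length(dfs) + 1L]] <<- cc$df
      cc$hw
    }
    hw <- add(m$sub$stem$complexity(hw))
    hws <- list()
    for (i in 1:4) {
      hw <- add(m$sub[[paste0("stage", i)]]$complexity(hw))
      hws[[i]] <- hw
    }
    phw <- hws[2:4]
    for (i in 1:3) add(m$sub[[paste0("lat", i)]]$complexity(phw[[i]]))
    for (r in seq_len(m$cfg$bifpn_repeats)) {
      p <- paste0("fpn", r)
      add(m$sub[[paste0(p, ".td4")]]$complexity(phw[[2]]))
      add(m$sub[[paste0(p, ".td3")]]$complexity(phw[[1]]))
      add(m$sub[[paste0(p, ".down3")]]$complexity(phw[[1]]))
      add(m$sub[[paste0(p, ".bu4")]]$complexity(phw[[2]]))
      add(m$sub[[paste0(p, ".down4")]]$complexity(phw[[2]]))
      add(m$sub[[paste0(p, ".bu5")]]$complexity(phw[[3]]))
    }
    for (i in 1:3) {
      add(m$sub[[paste0("out", i)]]$complexity(phw[[i]]))
      add(m$sub[[paste0("reg", i)]]$complexity(phw[[i]]))
      add(m$sub[[paste0("cls", i)]]$complexity(phw[[i]]))
    }
    list(df = do.call(rbind, dfs), hw = hw)
  }
  class(m) <- c("od_model", class(m))
  m
}

#' Fast normalized feature fusion
#'
#' The fusion stage of one pyramid node:
#' `O = sum_i max(w_i, 0) * I_i / (sum_j max(w_j, 0) + eps)`.  Inside the
#' network every fusion is followed by a depthwise-separable convolution;
#' this function exposes the fusion stage itself.
#'
#' @param inputs list of equal-shaped numeric arrays.
#' @param weights numeric vector, one weight per input; clamped at zero.
#' @param eps stabilizer in the denominator.
#' @return array of the common input shape.
#' @export
bifpn_fuse <- function(inputs, weights, eps = 1e-4) {
  if (length(inputs) != length(weights))
    stop("bifpn_fuse: need exactly one weight per input")
  d1 <- dim(inputs[[1]])
  for (x in inputs)
    if (!identical(dim(x), d1))
      stop("bifpn_fuse: all inputs must share one shape")
  rw <- pmax(weights, 0)
  S <- sum(rw) + eps
  Reduce(`+`, Map(function(x, a) a * x, inputs, rw / S))
}

# ---- decode + NMS ---------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Decode raw head outputs into detections
#'
#' Per feature-map cell, the class score is the maximum sigmoid class
#' activation; each box side distance is the expectation over the regmax
#' softmax bins, scaled by the level stride and anchored at the cell
#' center.  Boxes are clipped to the image.
#'
#' @param raw list of 3 levels, each `list(reg =, cls =)` arrays of dim
#'   `(4*regmax, H, W)` / `(num_classes, H, W)` (a trailing batch axis of
#'   size 1 is accepted).
#' @param conf_threshold minimum class score to keep.
#' @param img_size image side length in pixels.
#' @param strides level strides.
#' @param regmax number of distance bins per side.
#' @return data frame with columns x1, y1, x2, y2, score, class_id
#'   (0-based), ordered by decreasing score.
#' @export
decode_predictions <- function(raw, conf_threshold = 0.25, img_size,
                               strides = c(8L, 16L, 32L), regmax = 16L) {
  out <- list()
  for (li in seq_along(raw)) {
    reg <- ag_value(raw[[li]]$reg)
    cls <- ag_value(raw[[li]]$cls)
    if (length(dim(reg)) == 4L) {
      d <- dim(reg); reg <- array(reg[, , , 1], d[1:3])
    }
    if (length(dim(cls)) == 4L) {
      d <- dim(cls); cls <- array(cls[, , , 1], d[1:3])
    }
    s <- strides[li]
    h <- dim(reg)[2]
    w <- dim(reg)[3]
    ncell <- h * w
    # cells as columns: (4*regmax) x ncell
    regm <- matrix(reg, nrow = dim(reg)[1])
    clsm <- matrix(cls, nrow = dim(cls)[1])
    p <- 1 / (1 + exp(-clsm))
    score <- apply(p, 2, max)
    class_id <- max.col(t(p), ties.method = "first") - 1L
    keep <- which(score >= conf_threshold)
    if (length(keep) == 0) next
    # expectation over bins for each of the 4 sides
    dist <- matrix(0, nrow = 4, ncol = length(keep))
    bins <- 0:(regmax - 1)
    for (side in 1:4) {
      z <- t(regm[(side - 1) * regmax + seq_len(regmax), keep, drop = FALSE])
      pr <- softmax_rows(z)
      dist[side, ] <- as.vector(pr %*% bins)
    }
    idx <- keep - 1L
    cy <- (idx %% h) + 0.5
    cx <- (idx %/% h) + 0.5
    x1 <- (cx - dist[1, ]) * s
    y1 <- (cy - dist[2, ]) * s
    x2 <- (cx + dist[3, ]) * s
    y2 <- (cy + dist[4, ]) * s
    out[[length(out) + 1L]] <- data.frame(
      x1 = pmin(pmax(x1, 0), img_size), y1 = pmin(pmax(y1, 0), img_size),
      x2 = pmin(pmax(x2, 0), img_size), y2 = pmin(pmax(y2, 0), img_size),
      score = score[keep], class_id = class_id[keep])
  }
  if (length(out) == 0)
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), score = numeric(),
                      class_id = integer()))
  d <- do.call(rbind, out)
  d[order(-d$score), , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Detections are visited in order of decreasing score (ties broken by
#' original index); a kept box suppresses later boxes of the same class
#' whose IoU with it exceeds `iou_threshold`.
#'
#' @param dets data frame with x1, y1, x2, y2, score, class_id.
#' @param iou_threshold suppression threshold in `[0, 1]`.
#' @return the surviving subset, ordered by decreasing score.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0) return(dets)
  ord <- order(-dets$score, seq_len(nrow(dets)))
  d <- dets[ord, , drop = FALSE]
  n <- nrow(d)
  keep <- logical(n)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i == n) break
    rest <- which(alive & seq_len(n) > i & d$class_id == d$class_id[i])
    if (length(rest) == 0) next
    ious <- box_iou_one_many(as.numeric(d[i, 1:4]),
                             as.matrix(d[rest, 1:4]))
    alive[rest[ious > iou_threshold]] <- FALSE
  }
  d[keep, , drop = FALSE]
}

box_iou_one_many <- function(a, B) {
  ix1 <- pmax(a[1], B[, 1]); iy1 <- pmax(a[2], B[, 2])
  ix2 <- pmin(a[3], B[, 3]); iy2 <- pmin(a[4], B[, 4])
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aa <- max(a[3] - a[1], 0) * max(a[4] - a[2], 0)
  ab <- pmax(B[, 3] - B[, 1], 0) * pmax(B[, 4] - B[, 2], 0)
  u <- aa + ab - inter
  ifelse(u > 0, inter / u, 0)
}

# ---- checkpoints ----------------------------------------------------------

#' Save model weights to a checkpoint file
#'
#' Single-file versioned checkpoint holding the configuration, every
#' parameter, normalization running statistics, and bookkeeping fields.
#'
#' @param model an `od_model`.
#' @param path destination file.
#' @param epoch,seed optional bookkeeping values stored in the header.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            seed = NA_integer_) {
  ps <- od_parameters(model)
  bn <- od_bn_states(model)
  obj <- list(format = "orcharddet-checkpoint", version = 1L,
              cfg = unclass(model$cfg),
              params = lapply(ps, function(p) p$value),
              bn = lapply(bn, function(s)
                list(running_mean = s$running_mean,
                     running_var = s$running_var)),
              epoch = epoch, seed = seed)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model from a checkpoint file
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return an `od_model` with restored weights and statistics.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "orcharddet-checkpoint"))
    stop("not an orcharddet checkpoint: ", path)
  model <- build_model(do.call(model_config, obj$cfg))
  ps <- od_parameters(model)
  for (nm in names(obj$params)) {
    if (is.null(ps[[nm]])) stop("checkpoint parameter not in model: ", nm)
    ps[[nm]]$value <- obj$params[[nm]]
  }
  bn <- od_bn_states(model)
  for (nm in names(obj$bn)) {
    bn[[nm]]$running_mean <- obj$bn[[nm]]$running_mean
    bn[[nm]]$running_var <- obj$bn[[nm]]$running_var
  }
  model$checkpoint_meta <- list(epoch = obj$epoch, seed = obj$seed)
  model
}
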