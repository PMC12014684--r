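# SGD training with linear warm-up and the evaluation driver.

#' Training configuration
#'
#' Defaults mirror the conventional single-stage detector recipe: 200
#' epochs, batch 16, initial learning rate 0.01 with a flat final rate
#' (`lrf = 1` keeps the final learning rate equal to the initial one; set
#' `lrf < 1` for linear decay to `lr0 * lrf`), SGD momentum 0.937, weight
#' decay 5e-4, 3 warm-up epochs starting from momentum 0.8 and bias
#' learning rate 0.1.
#'
#' @param epochs,batch,lr0,lrf,momentum,weight_decay training scalars.
#' @param warmup_epochs,warmup_momentum,warmup_bias_lr warm-up schedule.
#' @param imgsz square training image size in pixels.
#' @param seed master seed for init, shuffling, and augmentation.
#' @param eval_every run validation every this many epochs (0 = only at the
#'   end).
#' @param augment apply random augmentation to training samples.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch = 16L, lr0 = 0.01, lrf = 1.0,
                         momentum = 0.937, weight_decay = 5e-4,
                         warmup_epochs = 3.0, warmup_momentum = 0.8,
                         warmup_bias_lr = 0.1, imgsz = 640L, seed = 0L,
                         eval_every = 1L, augment = FALSE) {
  stopifnot(epochs >= 1, batch >= 1, lr0 > 0, lrf > 0, momentum >= 0,
            momentum < 1, weight_decay >= 0, warmup_epochs >= 0,
            imgsz >= 32)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr0 = lr0, lrf = lrf, momentum = momentum,
                 weight_decay = weight_decay, warmup_epochs = warmup_epochs,
                 warmup_momentum = warmup_momentum,
                 warmup_bias_lr = warmup_bias_lr, imgsz = as.integer(imgsz),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 augment = augment),
            class = "train_config")
}

load_sample <- function(img_path, lab_path, imgsz) {
  img <- read_ppm(img_path)
  boxes <- if (file.exists(lab_path)) read_yolo_labels(lab_path)
           else empty_boxes()
  s <- list(image = img, boxes = boxes)
  if (!all(dim(img)[1:2] == imgsz)) s <- letterbox(s, imgsz)
  s
}

sample_to_target <- function(boxes, imgsz) {
  if (is.null(boxes) || nrow(boxes) == 0)
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), class_id = integer()))
  data.frame(x1 = (boxes$cx - boxes$w / 2) * imgsz,
             y1 = (boxes$cy - boxes$h / 2) * imgsz,
             x2 = (boxes$cx + boxes$w / 2) * imgsz,
             y2 = (boxes$cy + boxes$h / 2) * imgsz,
             class_id = boxes$class_id)
}

stack_images <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, dim = c(3L, d[1], d[2], n))
  for (i in seq_len(n)) x[, , , i] <- aperm(samples[[i]]$image, c(3, 1, 2))
  x
}

# learning-rate / momentum schedule: linear warm-up over warmup_epochs
# (learning rate from 0, bias group from warmup_bias_lr, momentum from
# warmup_momentum), then the per-epoch linear annealing lr0 -> lr0 * lrf.
lr_schedule <- function(cfg, steps_per_epoch) {
  nw <- max(round(cfg$warmup_epochs * steps_per_epoch), 1)
  lr_epoch <- function(epoch) {
    lf <- if (cfg$epochs == 1) 1
          else 1 + (cfg$lrf - 1) * (epoch - 1) / (cfg$epochs - 1)
    cfg$lr0 * lf
  }
  at <- function(step, epoch) {
    lr_e <- lr_epoch(epoch)
    if (cfg$warmup_epochs > 0 && step <= nw) {
      fr <- step / nw
      list(main = lr_e * fr,
           bias = cfg$warmup_bias_lr + (lr_e - cfg$warmup_bias_lr) * fr,
           momentum = cfg$warmup_momentum +
             (cfg$momentum - cfg$warmup_momentum) * fr)
    } else {
      list(main = lr_e, bias = lr_e, momentum = cfg$momentum)
    }
  }
  list(at = at, lr_epoch = lr_epoch, n_warmup = nw)
}

sgd_step <- function(opt, params, lr_main, lr_bias, mom, weight_decay) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    decayed <- length(dim(p$value)) == 4L  # conv kernels only
    if (decayed && weight_decay > 0) g <- g + weight_decay * p$value
    lr <- if (endsWith(nm, ".b")) lr_bias else lr_main
    buf <- opt[[nm]]
    buf <- if (is.null(buf)) g else mom * buf + g
    opt[[nm]] <- buf
    p$value <- p$value - lr * buf
    p$grad <- NULL
  }
  invisible(NULL)
}

#' Train the detector
#'
#' Plain SGD with momentum and weight decay (conv kernels only); linear
#' warm-up of the learning rate (bias parameters from `warmup_bias_lr`)
#' and of momentum over `warmup_epochs`; learning rate annealed linearly
#' from `lr0` to `lr0 * lrf` across epochs.  All randomness (weight init,
#' shuffling, augmentation) derives from `cfg$seed`.  The checkpoint with
#' the best validation mAP50-95 is retained alongside the last.
#'
#' @param model_cfg a [model_config()] (or an already built `od_model`).
#' @param data path to a dataset manifest (see [write_manifest()]).
#' @param cfg a [train_config()].
#' @param out_dir directory for checkpoints and the JSONL log.
#' @param verbose print per-epoch lines.
#' @return list with `best` and `last` checkpoint paths, `log` (one row
#'   per epoch: losses and, on evaluation epochs, metrics), and `model`.
#' @export
train <- function(model_cfg, data, cfg = train_config(),
                  out_dir = tempfile("run_"), verbose = FALSE) {
  manifest <- if (is.character(data)) read_manifest(data) else data
  files <- split_files(manifest, "train")
  if (nrow(files) == 0) stop("train: empty training split")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  model <- if (inherits(model_cfg, "od_model")) model_cfg
           else build_model(model_cfg, seed = cfg$seed)
  mcfg <- model$cfg
  params <- od_parameters(model)
  opt <- new.env(parent = emptyenv())

  nb <- ceiling(nrow(files) / cfg$batch)
  sched <- lr_schedule(cfg, nb)
  # cache decoded samples (datasets at desk scale fit in memory)
  cache <- lapply(seq_len(nrow(files)), function(i)
    load_sample(files$image[i], files$label[i], cfg$imgsz))

  log <- list()
  best_map <- -Inf
  best_path <- file.path(out_dir, "best.ckpt")
  last_path <- file.path(out_dir, "last.ckpt")
  log_path <- file.path(out_dir, "log.jsonl")
  step <- 0L
  epoch_seeds <- derive_seeds(cfg$seed, cfg$epochs, salt = 17L)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(epoch_seeds[epoch], sample(nrow(files)))
    lr_e <- sched$lr_epoch(epoch)
    esum <- c(box = 0, cls = 0, dfl = 0, total = 0)
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch + 1):min(b * cfg$batch, nrow(files))]
      samples <- cache[idx]
      if (isTRUE(cfg$augment)) {
        aseeds <- derive_seeds(epoch_seeds[epoch], length(idx), salt = b)
        samples <- lapply(seq_along(samples), function(i)
          augment(samples[[i]], seed = aseeds[i]))
      }
      x <- stack_images(samples)
      tg <- lapply(samples, function(s) sample_to_target(s$boxes, cfg$imgsz))

      step <- step + 1L
      at <- sched$at(step, epoch)
      lr_main <- at$main
      lr_bias <- at$bias
      mom <- at$momentum

      ag_tape_start()
      out <- model$forward(x, training = TRUE)
      lb <- detection_loss(out, tg, cfg$imgsz, regmax = mcfg$regmax,
                           strides = mcfg$strides)
      if (!is.finite(lb$total))
        stop("train: non-finite loss at epoch ", epoch, ", batch ", b,
             " - diverged")
      ag_backward(NULL)
      ag_tape_stop()
      sgd_step(opt, params, lr_main, lr_bias, mom, cfg$weight_decay)
      esum <- esum + c(lb$box, lb$cls, lb$dfl, lb$total) / nb
    }

    row <- list(epoch = epoch, lr = lr_e, box = esum[["box"]],
                cls = esum[["cls"]], dfl = esum[["dfl"]],
                total = esum[["total"]])
    do_eval <- cfg$eval_every > 0 && (epoch %% cfg$eval_every == 0)
    if (do_eval) {
      rep <- tryCatch(evaluate(model, manifest, split = "val",
                               imgsz = cfg$imgsz),
                      error = function(e) NULL)
      if (!is.null(rep)) {
        row$map50 <- rep$map50
        row$map50_95 <- rep$map50_95
        if (rep$map50_95 >= best_map) {
          best_map <- rep$map50_95
          save_checkpoint(model, best_path, epoch = epoch, seed = cfg$seed)
        }
      }
    }
    log[[epoch]] <- row
    cat(jsonlite::toJSON(row, auto_unbox = TRUE), "\n",
        file = log_path, append = epoch > 1, sep = "")
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f%s", epoch, cfg$epochs,
                      row$total,
                      if (!is.null(row$map50))
                        sprintf("  mAP50 %.3f  mAP50-95 %.3f",
                                row$map50, row$map50_95) else ""))
  }
  save_checkpoint(model, last_path, epoch = cfg$epochs, seed = cfg$seed)
  if (!file.exists(best_path))
    save_checkpoint(model, best_path, epoch = cfg$epochs, seed = cfg$seed)
  log_df <- do.call(rbind, lapply(log, function(r)
    as.data.frame(r[c("epoch", "lr", "box", "cls", "dfl", "total")])))
  list(best = best_path, last = last_path, log = log_df, model = model)
}

#' Evaluate a model on one dataset split
#'
#' Runs decode and non-maximum suppression on every image of the split and
#' computes the full metrics suite.  Deterministic given the weights.
#'
#' @param model an `od_model` or a checkpoint path.
#' @param data manifest path or list.
#' @param split one of "train", "val", "test".
#' @param conf decode confidence threshold (kept low so the
#'   precision-recall curve is fully sampled).
#' @param iou_nms suppression threshold.
#' @param imgsz evaluation image size.
#' @return a `metrics_report` (see [map_suite()]).
#' @export
evaluate <- function(model, data, split = "val", conf = 0.001,
                     iou_nms = 0.45, imgsz = 256L) {
  if (is.character(model)) model <- load_checkpoint(model)
  manifest <- if (is.character(data)) read_manifest(data) else data
  files <- split_files(manifest, split)
  if (nrow(files) == 0) stop("evaluate: split '", split, "' is empty")
  mcfg <- model$cfg
  dets <- list()
  gts <- list()
  for (i in seq_len(nrow(files))) {
    s <- load_sample(files$image[i], files$label[i], imgsz)
    x <- stack_images(list(s))
    out <- model$forward(x, training = FALSE)
    d <- decode_predictions(out, conf_threshold = conf, img_size = imgsz,
                            strides = mcfg$strides, regmax = mcfg$regmax)
    d <- nms(d, iou_nms)
    if (nrow(d) > 0) {
      d$image_id <- i
      dets[[length(dets) + 1L]] <- d
    }
    g <- sample_to_target(s$boxes, imgsz)
    if (nrow(g) > 0) {
      g$image_id <- i
      gts[[length(gts) + 1L]] <- g
    }
  }
  gts <- if (length(gts)) do.call(rbind, gts) else
    stop("evaluate: no ground-truth boxes in split '", split, "'")
  dets <- if (length(dets)) do.call(rbind, dets) else empty_dets()
  map_suite(dets, gts)
}
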