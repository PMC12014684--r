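# Detection loss, schedules, and the training/evaluation drivers.

ns <- asNamespace("orcharddet")

# one-level raw predictions on a small grid, as plain arrays
toy_raw <- function(R = 8L, h = 8L, w = 8L, nc = 1L, n = 1L, reg = NULL,
                    cls = NULL) {
  if (is.null(reg)) reg <- array(0, c(4 * R, h, w, n))
  if (is.null(cls)) cls <- array(0, c(nc, h, w, n))
  list(list(reg = reg, cls = cls))
}

test_that("empty-target batch: classification loss only, finite", {
  lb <- detection_loss(toy_raw(), list(data.frame()), imgsz = 64,
                       regmax = 8L, strides = 8L, backprop = FALSE)
  expect_equal(lb$box, 0)
  expect_equal(lb$dfl, 0)
  expect_gt(lb$cls, 0)
  expect_true(is.finite(lb$total))
  # zero logits: every cell contributes -log(sigmoid(0)) = log 2
  expect_equal(lb$cls, 64 * log(2))
})

test_that("a matching confident prediction scores lower than random init", {
  set.seed(60)
  R <- 8L
  tg <- list(data.frame(x1 = 16, y1 = 16, x2 = 48, y2 = 48, class_id = 0L))
  # aligned: cells predict the right box via one-hot bins, high class score
  # inside the target, low outside
  reg <- array(0, c(4 * R, 8, 8, 1))
  cls <- array(-8, c(1, 8, 8, 1))
  for (cr in 1:8) for (cc in 1:8) {
    cx <- (cc - 0.5) * 8; cy <- (cr - 0.5) * 8
    if (cx > 16 && cx < 48 && cy > 16 && cy < 48) {
      d <- round(c(cx - 16, cy - 16, 48 - cx, 48 - cy) / 8)
      for (side in 1:4)
        reg[(side - 1) * R + d[side] + 1, cr, cc, 1] <- 12
      cls[1, cr, cc, 1] <- 8
    }
  }
  good <- detection_loss(toy_raw(reg = reg, cls = cls), tg, imgsz = 64,
                         regmax = R, strides = 8L, backprop = FALSE)
  rnd <- detection_loss(
    toy_raw(reg = array(rnorm(4 * R * 64), c(4 * R, 8, 8, 1)),
            cls = array(rnorm(64), c(1, 8, 8, 1))),
    tg, imgsz = 64, regmax = R, strides = 8L, backprop = FALSE)
  expect_lt(good$total, rnd$total)
})

test_that("loss gradients on the raw maps match numerical differences", {
  set.seed(61)
  R <- 4L; h <- 4L; w <- 4L
  reg <- array(rnorm(4 * R * h * w, sd = 0.5), c(4 * R, h, w, 1))
  cls <- array(rnorm(h * w, sd = 0.5), c(1, h, w, 1))
  tg <- list(data.frame(x1 = 4, y1 = 6, x2 = 26, y2 = 24, class_id = 0L))
  # freeze the cell-to-target assignment so the loss is an exactly
  # differentiable function of the raw maps (the soft targets are constants
  # of the step by design)
  az <- detection_loss(toy_raw(R, h, w, reg = reg, cls = cls), tg,
                       imgsz = 32, regmax = R, strides = 8L,
                       backprop = FALSE)$assignments
  loss_of <- function(regv, clsv) {
    detection_loss(toy_raw(R, h, w, reg = regv, cls = clsv), tg, imgsz = 32,
                   regmax = R, strides = 8L, backprop = FALSE,
                   assignments = az)$total
  }
  ns$ag_tape_start()
  rn <- ns$ag_node(reg)
  cn <- ns$ag_node(cls)
  detection_loss(list(list(reg = rn, cls = cn)), tg, imgsz = 32,
                 regmax = R, strides = 8L, backprop = TRUE,
                 assignments = az)
  ns$ag_tape_stop()
  eps <- 1e-5
  # probe a handful of coordinates in each map
  for (i in sample(length(reg), 12)) {
    rp <- reg; rm <- reg
    rp[i] <- rp[i] + eps; rm[i] <- rm[i] - eps
    want <- (loss_of(rp, cls) - loss_of(rm, cls)) / (2 * eps)
    expect_equal(rn$grad[i], want, tolerance = 5e-3)
  }
  for (i in sample(length(cls), 6)) {
    cp <- cls; cm <- cls
    cp[i] <- cp[i] + eps; cm[i] <- cm[i] - eps
    want <- (loss_of(reg, cp) - loss_of(reg, cm)) / (2 * eps)
    expect_equal(cn$grad[i], want, tolerance = 5e-3)
  }
})

test_that("loss is finite and non-negative on randomized batches", {
  set.seed(62)
  for (case in 1:25) {
    R <- sample(c(4L, 8L), 1)
    n <- sample(1:2, 1)
    reg <- array(rnorm(4 * R * 16 * n, sd = 2), c(4 * R, 4, 4, n))
    cls <- array(rnorm(2 * 16 * n, sd = 2), c(2, 4, 4, n))
    tg <- lapply(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(data.frame())
      b <- rand_boxes(k, S = 32, classes = c(0L, 1L), min_side = 4)
      b[, c("x1", "y1", "x2", "y2", "class_id")]
    })
    lb <- detection_loss(list(list(reg = reg, cls = cls)), tg, imgsz = 32,
                         regmax = R, strides = 8L, backprop = FALSE)
    expect_true(all(is.finite(c(lb$box, lb$cls, lb$dfl, lb$total))))
    expect_gte(lb$box, 0)
    expect_gte(lb$cls, 0)
    expect_gte(lb$dfl, 0)
    expect_equal(lb$total,
                 7.5 * lb$box + 0.5 * lb$cls + 1.5 * lb$dfl,
                 tolerance = 1e-12)
  }
})

test_that("20 gradient steps on one fixed batch strictly reduce the loss", {
  set.seed(63)
  cfg <- model_config(num_classes = 1, width_mult = 0.125,
                      stage_blocks = c(1, 1, 1, 1), bifpn_channels = 8,
                      bifpn_repeats = 1, regmax = 8)
  m <- build_model(cfg, seed = 3)
  params <- ns$od_parameters(m)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
  tg <- list(data.frame(x1 = 12, y1 = 12, x2 = 44, y2 = 44, class_id = 0L))
  opt <- new.env()
  losses <- numeric(21)
  for (step in 0:20) {
    ns$ag_tape_start()
    out <- m$forward(x, training = TRUE)
    lb <- detection_loss(out, tg, 64, regmax = cfg$regmax,
                         strides = cfg$strides)
    losses[step + 1] <- lb$total
    ns$ag_backward(NULL)
    ns$ag_tape_stop()
    ns$sgd_step(opt, params, 0.01, 0.01, 0.9, 0)
    # gradients are consumed and reset by the step
    expect_true(all(vapply(params, function(p) is.null(p$grad),
                           logical(1))))
  }
  expect_lt(losses[21], losses[1])
  expect_true(all(is.finite(losses)))
})

test_that("warmup joins the annealing curve continuously", {
  cfg <- train_config(epochs = 10, batch = 4, lr0 = 0.01, lrf = 0.2,
                      warmup_epochs = 3)
  nb <- 5L
  sch <- ns$lr_schedule(cfg, nb)
  expect_equal(sch$n_warmup, 15L)
  # warmup starts at the configured anchors
  first <- sch$at(1, 1)
  expect_equal(first$main, sch$lr_epoch(1) / 15)
  expect_lt(abs(first$bias - cfg$warmup_bias_lr), 0.01)
  expect_lt(abs(first$momentum - cfg$warmup_momentum), 0.01)
  # last warmup step equals the annealed value at that epoch: continuity
  eps_epoch <- 3
  last <- sch$at(15, eps_epoch)
  after <- sch$at(16, eps_epoch)
  expect_equal(last$main, sch$lr_epoch(eps_epoch))
  expect_equal(last$bias, sch$lr_epoch(eps_epoch))
  expect_equal(last$momentum, cfg$momentum)
  expect_equal(after$main, sch$lr_epoch(eps_epoch))
  # linear annealing endpoints
  expect_equal(sch$lr_epoch(1), 0.01)
  expect_equal(sch$lr_epoch(10), 0.01 * 0.2)
})

make_tiny_dataset <- function(n, seed, size = 64) {
  out <- tempfile("ds_")
  p <- scene_params(image_size = size, n_fruits = c(1, 2),
                    radius_range = c(10, 16), occluder_prob = 0,
                    cluster_prob = 0, brightness_range = c(0.95, 1.05))
  generate_dataset(n, p, out, ratios = c(0.6, 0.2, 0.2), seed = seed)
}

test_that("training smoke: two epochs emit two log rows and a checkpoint", {
  man <- make_tiny_dataset(10, seed = 70)
  mcfg <- model_config(num_classes = 1, width_mult = 0.125,
                       stage_blocks = c(1, 1, 1, 1), bifpn_channels = 8,
                       bifpn_repeats = 1, regmax = 8)
  tcfg <- train_config(epochs = 2, batch = 4, imgsz = 64, seed = 70,
                       eval_every = 1)
  dir <- tempfile("run_")
  res <- train(mcfg, man, tcfg, out_dir = dir)
  expect_equal(nrow(res$log), 2)
  expect_true(file.exists(res$best))
  expect_true(file.exists(res$last))
  expect_true(file.exists(file.path(dir, "log.jsonl")))
  expect_equal(length(readLines(file.path(dir, "log.jsonl"))), 2)
  unlink(dir, recursive = TRUE)
})

test_that("training is deterministic: identical epoch-1 loss on reruns", {
  man <- make_tiny_dataset(8, seed = 71)
  mcfg <- model_config(num_classes = 1, width_mult = 0.125,
                       stage_blocks = c(1, 1, 1, 1), bifpn_channels = 8,
                       bifpn_repeats = 1, regmax = 8)
  tcfg <- train_config(epochs = 1, batch = 4, imgsz = 64, seed = 71,
                       eval_every = 0)
  r1 <- train(mcfg, man, tcfg, out_dir = tempfile())
  r2 <- train(mcfg, man, tcfg, out_dir = tempfile())
  expect_identical(r1$log$total, r2$log$total)
})

test_that("evaluation: untrained is near zero, oracle detections are 1.0", {
  man <- make_tiny_dataset(10, seed = 72)
  mcfg <- model_config(num_classes = 1, width_mult = 0.125,
                       stage_blocks = c(1, 1, 1, 1), bifpn_channels = 8,
                       bifpn_repeats = 1, regmax = 8)
  m <- build_model(mcfg, seed = 72)
  rep <- evaluate(m, man, split = "train", imgsz = 64)
  expect_lt(rep$map50, 0.1)
  # identical checkpoint, identical report
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, ck)
  rep2 <- evaluate(ck, man, split = "train", imgsz = 64)
  expect_equal(rep$map50, rep2$map50)
  expect_equal(rep$per_class_ap, rep2$per_class_ap)

  # perfect-oracle detections injected in place of model output
  manifest <- read_manifest(man)
  files <- orcharddet:::split_files(manifest, "train")
  gts <- do.call(rbind, lapply(seq_len(nrow(files)), function(i) {
    g <- orcharddet:::sample_to_target(read_yolo_labels(files$label[i]), 64)
    if (nrow(g)) g$image_id <- i
    g
  }))
  dets <- gts
  dets$score <- 0.99
  perfect <- map_suite(dets, gts)
  expect_equal(perfect$map50, 1)
  expect_equal(perfect$map50_95, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_error(evaluate(m, man, split = "nosuch"), "empty|nosuch")
})
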