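# Detector assembly: shape/channel contracts, fusion, decode, NMS.

tiny_cfg <- function(num_classes = 1L, regmax = 8L,
                     bifpn_repeats = 1L) {
  model_config(num_classes = num_classes, width_mult = 0.125,
               stage_blocks = c(1, 1, 1, 1), bifpn_channels = 8L,
               bifpn_repeats = bifpn_repeats, regmax = regmax)
}

test_that("raw prediction maps follow the stride and channel contracts", {
  set.seed(40)
  ns <- asNamespace("orcharddet")
  m <- build_model(tiny_cfg(num_classes = 1L, regmax = 16L), seed = 1)
  x <- array(runif(3 * 128 * 128), c(3, 128, 128, 1))
  out <- m$forward(x)
  sizes <- t(vapply(out, function(l) dim(ns$ag_value(l$reg))[2:3],
                    integer(2)))
  expect_equal(sizes, matrix(c(16, 16, 8, 8, 4, 4), ncol = 2, byrow = TRUE))
  # 4 x regmax regression channels, num_classes classification channels
  expect_equal(vapply(out, function(l) dim(ns$ag_value(l$reg))[1],
                      integer(1)), rep(64L, 3))
  expect_equal(vapply(out, function(l) dim(ns$ag_value(l$cls))[1],
                      integer(1)), rep(1L, 3))
})

test_that("channel contract holds across a randomized config suite", {
  ns <- asNamespace("orcharddet")
  set.seed(41)
  for (case in 1:5) {
    nc <- sample(1:4, 1)
    rm <- sample(c(4L, 8L, 16L), 1)
    m <- build_model(tiny_cfg(num_classes = nc, regmax = rm), seed = case)
    x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
    out <- m$forward(x)
    for (li in 1:3) {
      expect_equal(dim(ns$ag_value(out[[li]]$reg))[1], 4L * rm)
      expect_equal(dim(ns$ag_value(out[[li]]$cls))[1], nc)
      expect_equal(dim(ns$ag_value(out[[li]]$reg))[2],
                   64L %/% m$cfg$strides[li])
    }
  }
})

test_that("same seed gives identical weights; forward is deterministic", {
  ns <- asNamespace("orcharddet")
  m1 <- build_model(tiny_cfg(), seed = 99)
  m2 <- build_model(tiny_cfg(), seed = 99)
  p1 <- ns$od_parameters(m1)
  p2 <- ns$od_parameters(m2)
  expect_identical(names(p1), names(p2))
  for (nm in names(p1)) expect_identical(p1[[nm]]$value, p2[[nm]]$value)

  x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
  o1 <- m1$forward(x)
  o2 <- m1$forward(x)
  expect_identical(ns$ag_value(o1[[1]]$reg), ns$ag_value(o2[[1]]$reg))
  expect_identical(ns$ag_value(o1[[3]]$cls), ns$ag_value(o2[[3]]$cls))
})

test_that("model_config rejects invalid fields", {
  expect_error(model_config(num_classes = 0), "num_classes")
  expect_error(model_config(regmax = 1), "regmax")
  expect_error(model_config(strides = c(8, 16, 24)), "strides")
  expect_error(model_config(stage_blocks = c(1, 2)), "stage_blocks")
  expect_error(model_config(bifpn_channels = 7), "bifpn_channels")
})

test_that("bifpn_fuse is the clamped normalized weighted mean", {
  set.seed(42)
  X <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  # equal inputs, weights (1, 1): returns the input up to the eps shrink
  f <- bifpn_fuse(list(X, X), c(1, 1), eps = 1e-12)
  expect_equal(f, X, tolerance = 1e-9)
  # weights (1, 0) select the first input scaled by 1/(1+eps)
  Y <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  eps <- 1e-4
  expect_equal(bifpn_fuse(list(X, Y), c(1, 0), eps = eps), X / (1 + eps))
  # negative weights are clamped to zero
  expect_equal(bifpn_fuse(list(X, Y), c(1, -5), eps = eps), X / (1 + eps))
  # random 3-input case equals the hand-computed weighted mean
  Z <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  w <- c(0.2, 1.7, 0.6)
  ref <- (w[1] * X + w[2] * Y + w[3] * Z) / (sum(w) + eps)
  expect_equal(bifpn_fuse(list(X, Y, Z), w, eps = eps), ref)
  # fusion output is bounded by the shrunken input envelope
  lo <- pmin(X, Y, Z) * sum(w) / (sum(w) + eps)
  hi <- pmax(X, Y, Z) * sum(w) / (sum(w) + eps)
  got <- bifpn_fuse(list(X, Y, Z), w, eps = eps)
  expect_true(all(got >= pmin(lo, hi) - 1e-12 & got <= pmax(lo, hi) + 1e-12))
  expect_error(bifpn_fuse(list(X, Y[, 1:2, ]), c(1, 1)), "shape")
  expect_error(bifpn_fuse(list(X, Y), c(1, 1, 1)), "one weight per input")
})

make_raw <- function(reg, cls) {
  list(list(reg = reg, cls = cls))
}

test_that("decode: point-mass and uniform bin distributions", {
  R <- 8L
  h <- 4L; w <- 4L; stride <- 8L
  cls <- array(-20, c(1, h, w))
  cls[1, 2, 3] <- 20  # one confident cell at row 2, col 3
  # one-hot mass on bin b for every side (b small enough to avoid clipping)
  b <- 1L
  reg <- array(-50, c(4 * R, h, w))
  for (side in 1:4) reg[(side - 1) * R + b + 1, , ] <- 50
  d <- decode_predictions(make_raw(reg, cls), conf_threshold = 0.25,
                          img_size = h * stride, strides = stride,
                          regmax = R)
  expect_equal(nrow(d), 1)
  cx <- (3 - 1 + 0.5) * stride  # col -> x
  cy <- (2 - 1 + 0.5) * stride
  expect_equal(as.numeric(d[1, 1:4]),
               c(cx - b * stride, cy - b * stride,
                 cx + b * stride, cy + b * stride),
               tolerance = 1e-6)
  expect_equal(d$score, 1, tolerance = 1e-6)

  # uniform bins: expected distance (regmax - 1) / 2 per side
  reg0 <- array(0, c(4 * R, h, w))
  d0 <- decode_predictions(make_raw(reg0, cls), conf_threshold = 0.25,
                           img_size = h * stride, strides = stride,
                           regmax = R)
  expect_equal(as.numeric(d0[1, 3] - d0[1, 1]),
               min(cx + (R - 1) / 2 * stride, h * stride) -
                 max(cx - (R - 1) / 2 * stride, 0), tolerance = 1e-6)
})

test_that("decoded expectation equals the explicit sum over bins", {
  set.seed(43)
  R <- 8L; h <- 3L; w <- 3L; stride <- 8L
  reg <- array(rnorm(4 * R * h * w), c(4 * R, h, w))
  cls <- array(5, c(1, h, w))  # every cell confident
  d <- decode_predictions(make_raw(reg, cls), conf_threshold = 0.25,
                          img_size = 64, strides = stride, regmax = R)
  expect_equal(nrow(d), h * w)
  # check one specific cell (row 2, col 1) against a brute-force loop
  q <- order(-d$score)[1]  # scores all equal; use box arithmetic instead
  cellr <- 2; cellc <- 1
  z <- reg[, cellr, cellc]
  dist <- vapply(1:4, function(side) {
    zz <- z[(side - 1) * R + 1:R]
    p <- exp(zz - max(zz)); p <- p / sum(p)
    sum((0:(R - 1)) * p)
  }, numeric(1)) * stride
  cx <- (cellc - 0.5) * stride
  cy <- (cellr - 0.5) * stride
  want <- c(max(cx - dist[1], 0), max(cy - dist[2], 0),
            min(cx + dist[3], 64), min(cy + dist[4], 64))
  found <- FALSE
  for (i in seq_len(nrow(d)))
    if (max(abs(as.numeric(d[i, 1:4]) - want)) < 1e-9) found <- TRUE
  expect_true(found)
  # all decoded boxes are ordered and inside the image
  expect_true(all(d$x1 <= d$x2 & d$y1 <= d$y2))
  expect_true(all(d$x1 >= 0 & d$y1 >= 0 & d$x2 <= 64 & d$y2 <= 64))
})

test_that("nms: duplicates, disjoint boxes, and the brute-force oracle", {
  two <- data.frame(x1 = c(0, 0), y1 = c(0, 0), x2 = c(10, 10),
                    y2 = c(10, 10), score = c(0.9, 0.8), class_id = 0L)
  kept <- nms(two, 0.45)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  disj <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                     y2 = c(10, 60), score = c(0.9, 0.8), class_id = 0L)
  expect_equal(nrow(nms(disj, 0.01)), 2)

  set.seed(44)
  for (case in 1:20) {
    d <- rand_boxes(10, classes = c(0L, 1L))
    d$score <- runif(10)
    thr <- sample(c(0.3, 0.45, 0.6), 1)
    got <- nms(d, thr)
    ref <- nms_oracle(d, thr)
    expect_equal(got[order(got$score), ], ref[order(ref$score), ],
                 ignore_attr = TRUE)
    # antichain property: no two same-class survivors overlap above thr
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) for (j in (i + 1):nrow(got)) {
        if (got$class_id[i] == got$class_id[j])
          expect_lte(iou(as.numeric(got[i, 1:4]), as.numeric(got[j, 1:4])),
                     thr)
      }
    }
  }
})

test_that("checkpoints round-trip weights and running statistics", {
  ns <- asNamespace("orcharddet")
  m <- build_model(tiny_cfg(), seed = 5)
  # perturb one running stat so the round-trip is informative
  bn <- ns$od_bn_states(m)
  bn[[1]]$running_mean <- bn[[1]]$running_mean + 0.5
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path, epoch = 3L, seed = 5L)
  m2 <- load_checkpoint(path)
  expect_equal(m2$checkpoint_meta$epoch, 3L)
  x <- array(runif(3 * 64 * 64), c(3, 64, 64, 1))
  o1 <- m$forward(x)
  o2 <- m2$forward(x)
  expect_equal(ns$ag_value(o1[[1]]$reg), ns$ag_value(o2[[1]]$reg))
  expect_equal(ns$ag_value(o1[[2]]$cls), ns$ag_value(o2[[2]]$cls))
  unlink(path)
})
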