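# Label files, splitting, images, augmentation.

test_that("label files parse, validate, and round-trip to 1e-6", {
  p <- tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.2", p)
  b <- read_yolo_labels(p)
  expect_equal(nrow(b), 1)
  expect_equal(b$class_id, 0L)
  expect_equal(as.numeric(b[1, 2:5]), c(0.5, 0.5, 0.2, 0.2))

  # empty file <-> empty list
  writeLines(character(0), p)
  expect_equal(nrow(read_yolo_labels(p)), 0)
  write_yolo_labels(read_yolo_labels(p), p)
  expect_equal(nrow(read_yolo_labels(p)), 0)

  # round-trip of 50 random boxes
  set.seed(50)
  cx <- runif(50, 0.2, 0.8); cy <- runif(50, 0.2, 0.8)
  boxes <- data.frame(class_id = sample(0:2, 50, TRUE), cx = cx, cy = cy,
                      w = pmin(runif(50, 0.05, 0.3), 2 * pmin(cx, 1 - cx)),
                      h = pmin(runif(50, 0.05, 0.3), 2 * pmin(cy, 1 - cy)))
  write_yolo_labels(boxes, p)
  back <- read_yolo_labels(p)
  expect_equal(back$class_id, boxes$class_id)
  for (col in c("cx", "cy", "w", "h"))
    expect_true(all(abs(back[[col]] - boxes[[col]]) <= 1e-6))

  # malformed / out-of-range rows carry the line number
  writeLines(c("0 0.5 0.5 0.2 0.2", "0 0.5 oops 0.2 0.2"), p)
  expect_error(read_yolo_labels(p), ":2")
  writeLines("0 1.2 0.5 0.2 0.2", p)
  expect_error(read_yolo_labels(p), "out of")
  writeLines("0 0.5 0.5 0.2", p)
  expect_error(read_yolo_labels(p), "malformed")
  unlink(p)
})

test_that("writing clips box extents into [0, 1]", {
  p <- tempfile(fileext = ".txt")
  write_yolo_labels(data.frame(class_id = 0L, cx = 0.05, cy = 0.5,
                               w = 0.2, h = 0.2), p)
  b <- read_yolo_labels(p)
  expect_gte(b$cx - b$w / 2, 0)
  expect_equal(b$cx + b$w / 2, 0.15, tolerance = 1e-6)
  unlink(p)
})

test_that("split sizes follow largest-remainder apportionment", {
  s <- split_dataset(seq_len(1250), c(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(s[c("train", "val", "test")]),
               c(train = 1000L, val = 125L, test = 125L))
  s10 <- split_dataset(1:10, seed = 2)
  expect_equal(lengths(s10[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  expect_error(split_dataset(1:2, seed = 1), "at least 3")
  expect_error(split_dataset(1:10, c(0.5, 0.5, 0.5), seed = 1), "ratios")
})

test_that("splits are deterministic and exactly partition the ids", {
  s1 <- split_dataset(1:100, seed = 7)
  s2 <- split_dataset(1:100, seed = 7)
  expect_identical(s1, s2)
  set.seed(51)
  for (case in 1:30) {
    n <- sample(3:2000, 1)
    r <- runif(3, 0.1, 1)
    r <- r / sum(r)
    r[3] <- 1 - r[1] - r[2]
    s <- split_dataset(seq_len(n), r, seed = case)
    all_ids <- c(s$train, s$val, s$test)
    expect_equal(sort(all_ids), seq_len(n))  # exhaustive and disjoint
  }
})

test_that("ppm images round-trip in binary and ascii", {
  set.seed(52)
  img <- array(runif(12 * 9 * 3), c(12, 9, 3))
  q <- round(img * 255) / 255  # quantized reference
  p6 <- tempfile(fileext = ".ppm")
  write_ppm(img, p6)
  expect_equal(read_ppm(p6), q, tolerance = 1e-9)
  p3 <- tempfile(fileext = ".ppm")
  write_ppm(img, p3, ascii = TRUE)
  expect_equal(read_ppm(p3), q, tolerance = 1e-9)
  unlink(c(p6, p3))
})

test_that("letterbox preserves aspect and remaps boxes", {
  img <- array(0.2, c(20, 40, 3))  # wide image
  boxes <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.5, h = 0.5)
  out <- letterbox(list(image = img, boxes = boxes), 64)
  expect_equal(dim(out$image), c(64, 64, 3))
  # content occupies 32 rows centered; padding is gray
  expect_equal(out$image[1, 1, 1], 0.5)
  expect_equal(out$image[32, 32, 1], 0.2)
  # box: x untouched (full width scale), y compressed to the 32/64 band
  expect_equal(out$boxes$cx, 0.5)
  expect_equal(out$boxes$w, 0.5)
  expect_equal(out$boxes$h, 0.5 * 32 / 64)
})

test_that("augment: identity settings change nothing", {
  set.seed(53)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  boxes <- data.frame(class_id = 0L, cx = 0.5, cy = 0.4, w = 0.3, h = 0.2)
  id_params <- augment_params(rotate = 0, scale = c(1, 1),
                              hsv_gain = c(0, 0, 0))
  out <- augment(list(image = img, boxes = boxes), id_params, seed = 1)
  expect_equal(out$image, img)
  expect_equal(out$boxes, boxes)
})

test_that("augment: pure scaling transforms boxes affinely", {
  set.seed(54)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  boxes <- data.frame(class_id = 0L, cx = 0.6, cy = 0.3, w = 0.2, h = 0.2)
  half <- augment_params(rotate = 0, scale = c(0.5, 0.5),
                         hsv_gain = c(0, 0, 0), min_area = 0)
  out <- augment(list(image = img, boxes = boxes), half, seed = 2)
  expect_equal(out$boxes$w, 0.1, tolerance = 1e-9)
  expect_equal(out$boxes$h, 0.1, tolerance = 1e-9)
  # centers contract halfway toward the image center
  expect_equal(out$boxes$cx, 0.5 + (0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(out$boxes$cy, 0.5 + (0.3 - 0.5) / 2, tolerance = 1e-9)
})

test_that("augment: rotated boxes match the 4-corner affine oracle", {
  set.seed(55)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  for (case in 1:10) {
    cx <- runif(1, 0.3, 0.7); cy <- runif(1, 0.3, 0.7)
    boxes <- data.frame(class_id = 0L, cx = cx, cy = cy,
                        w = runif(1, 0.1, 0.3), h = runif(1, 0.1, 0.3))
    pr <- augment_params(rotate = 25, scale = c(0.7, 1.3),
                         hsv_gain = c(0, 0, 0), min_area = 0)
    out <- augment(list(image = img, boxes = boxes), pr, seed = case)
    # reproduce the sampled transform: same seed, same draw order
    draws <- withr::with_seed(case, {
      th <- runif(1, -25, 25) * pi / 180
      sc <- runif(1, 0.7, 1.3)
      c(th, sc)
    })
    th <- draws[1]; sc <- draws[2]
    S <- 48
    px <- c(cx - boxes$w / 2, cx + boxes$w / 2,
            cx + boxes$w / 2, cx - boxes$w / 2) * S
    py <- c(cy - boxes$h / 2, cy - boxes$h / 2,
            cy + boxes$h / 2, cy + boxes$h / 2) * S
    tx <- sc * (cos(th) * (px - S / 2) - sin(th) * (py - S / 2)) + S / 2
    ty <- sc * (sin(th) * (px - S / 2) + cos(th) * (py - S / 2)) + S / 2
    x1 <- max(min(tx), 0); x2 <- min(max(tx), S)
    y1 <- max(min(ty), 0); y2 <- min(max(ty), S)
    expect_equal(out$boxes$cx, (x1 + x2) / 2 / S, tolerance = 1e-9)
    expect_equal(out$boxes$cy, (y1 + y2) / 2 / S, tolerance = 1e-9)
    expect_equal(out$boxes$w, (x2 - x1) / S, tolerance = 1e-9)
    expect_equal(out$boxes$h, (y2 - y1) / S, tolerance = 1e-9)
  }
})

test_that("augment keeps labels in bounds and never adds labels", {
  set.seed(56)
  img <- array(runif(40 * 40 * 3), c(40, 40, 3))
  for (case in 1:15) {
    n <- sample(0:4, 1)
    cx <- runif(n, 0.1, 0.9); cy <- runif(n, 0.1, 0.9)
    boxes <- data.frame(class_id = rep(0L, n), cx = cx, cy = cy,
                        w = pmin(runif(n, 0.05, 0.4), 2 * pmin(cx, 1 - cx)),
                        h = pmin(runif(n, 0.05, 0.4), 2 * pmin(cy, 1 - cy)))
    out <- augment(list(image = img, boxes = boxes), augment_params(),
                   seed = case)
    expect_lte(nrow(out$boxes), n)
    if (nrow(out$boxes) > 0) {
      expect_true(all(out$boxes$cx - out$boxes$w / 2 >= -1e-9))
      expect_true(all(out$boxes$cx + out$boxes$w / 2 <= 1 + 1e-9))
      expect_true(all(out$boxes$cy - out$boxes$h / 2 >= -1e-9))
      expect_true(all(out$boxes$cy + out$boxes$h / 2 <= 1 + 1e-9))
    }
    # determinism under the seed
    out2 <- augment(list(image = img, boxes = boxes), augment_params(),
                    seed = case)
    expect_identical(out$image, out2$image)
    expect_identical(out$boxes, out2$boxes)
  }
})

test_that("manifest round-trips and pairs image/label files", {
  root <- tempfile("ds_")
  for (d in c("images", "labels"))
    for (s in c("train", "val", "test"))
      dir.create(file.path(root, d, s), recursive = TRUE)
  img <- array(0.5, c(8, 8, 3))
  write_ppm(img, file.path(root, "images", "train", "a.ppm"))
  write_yolo_labels(data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                               w = 0.2, h = 0.2),
                    file.path(root, "labels", "train", "a.txt"))
  man_path <- write_manifest(root, names = "fruit")
  man <- read_manifest(man_path)
  expect_equal(man$names, "fruit")
  files <- orcharddet:::split_files(man, "train")
  expect_equal(nrow(files), 1)
  expect_true(file.exists(files$label[1]))
  unlink(root, recursive = TRUE)
})
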