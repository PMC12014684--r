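# Dataset input/output in the YOLO directory dialect:
#   <root>/images/{train,val,test}/*.ppm
#   <root>/labels/{train,val,test}/*.txt   (rows: class cx cy w h, normalized)
# plus a YAML manifest naming the root, the split subdirectories, and the
# class list.  Images travel as (H, W, 3) arrays in [0, 1]; portable pixmap
# (PPM) is used for storage because it is simple, lossless, and text-
# friendly (both binary P6 and ASCII P3 are supported).

# ---- images ---------------------------------------------------------------

#' Write an image as PPM
#'
#' @param img (H, W, 3) array in `[0, 1]`.
#' @param path destination; parent directory must exist.
#' @param ascii write ASCII P3 instead of binary P6.
#' @export
write_ppm <- function(img, path, ascii = FALSE) {
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3)
  v <- as.integer(round(clamp(img, 0, 1) * 255))
  # interleave channels: for each pixel (row-major) r, g, b
  px <- aperm(array(v, d), c(3, 2, 1))  # (3, W, H) -> flatten = per-row pixels
  flat <- as.integer(px)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(d[2], d[1]), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", d[2], d[1]), con, eos = NULL)
    writeBin(as.raw(flat), con)
  }
  invisible(path)
}

#' Read a PPM image
#'
#' @param path a P6 (binary) or P3 (ASCII) portable pixmap.
#' @return (H, W, 3) array in `[0, 1]`.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P6", "P3")) stop("not a PPM file: ", path)
  toks <- character(0)
  while (length(toks) < 3) {
    ch <- readChar(con, 1)
    if (length(ch) == 0) stop("truncated PPM header: ", path)
    if (grepl("[[:space:]]", ch)) next
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1)
      if (length(ch) == 0 || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    toks <- c(toks, tok)
  }
  w <- as.integer(toks[1])
  h <- as.integer(toks[2])
  maxv <- as.integer(toks[3])
  n <- w * h * 3L
  if (magic == "P6") {
    flat <- as.integer(readBin(con, "raw", n))
  } else {
    flat <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  px <- array(flat, dim = c(3L, w, h))
  aperm(px, c(3, 2, 1)) / maxv
}

# nearest-neighbour resize of an (H, W, 3) image
resize_nearest <- function(img, out_h, out_w) {
  d <- dim(img)
  ih <- clamp(ceiling(seq_len(out_h) / out_h * d[1]), 1, d[1])
  iw <- clamp(ceiling(seq_len(out_w) / out_w * d[2]), 1, d[2])
  img[ih, iw, , drop = FALSE]
}

#' Letterbox an image to a square canvas
#'
#' Aspect-preserving resize followed by symmetric gray padding; boxes are
#' remapped to the canvas.
#'
#' @param sample list with `image` (H, W, 3) and `boxes` (normalized YOLO
#'   data frame as from [read_yolo_labels()]).
#' @param size target side length in pixels.
#' @param pad_value padding gray level.
#' @return a sample list at the target size.
#' @export
letterbox <- function(sample, size, pad_value = 0.5) {
  img <- sample$image
  d <- dim(img)
  r <- min(size / d[1], size / d[2])
  nh <- as.integer(round(d[1] * r))
  nw <- as.integer(round(d[2] * r))
  canvas <- array(pad_value, dim = c(size, size, 3))
  top <- (size - nh) %/% 2L
  left <- (size - nw) %/% 2L
  canvas[top + seq_len(nh), left + seq_len(nw), ] <-
    resize_nearest(img, nh, nw)
  boxes <- sample$boxes
  if (!is.null(boxes) && nrow(boxes) > 0) {
    boxes$cx <- (boxes$cx * nw + left) / size
    boxes$cy <- (boxes$cy * nh + top) / size
    boxes$w <- boxes$w * nw / size
    boxes$h <- boxes$h * nh / size
  }
  list(image = canvas, boxes = boxes)
}

# ---- labels ---------------------------------------------------------------

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric())
}

#' Read YOLO-format labels
#'
#' One row per object: `class cx cy w h`, whitespace-separated, coordinates
#' normalized to `[0, 1]`.  An empty file yields an empty box table.
#'
#' @param path label text file.
#' @return data frame with class_id, cx, cy, w, h.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- which(nzchar(lines))
  if (length(keep) == 0) return(empty_boxes())
  rows <- lapply(keep, function(i) {
    f <- strsplit(lines[i], "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(vals))
      stop("malformed label row at ", path, ":", i, ": '", lines[i], "'")
    if (vals[1] < 0 || vals[1] != round(vals[1]))
      stop("invalid class id at ", path, ":", i)
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stop("label coordinates out of [0,1] at ", path, ":", i)
    vals
  })
  m <- do.call(rbind, rows)
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write YOLO-format labels
#'
#' Box extents are clipped to `[0, 1]` before writing; values carry six
#' decimals, so write-then-read round-trips to 1e-6.
#'
#' @param boxes data frame with class_id, cx, cy, w, h (normalized).
#' @param path destination text file.
#' @export
write_yolo_labels <- function(boxes, path) {
  if (is.null(boxes) || nrow(boxes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  x1 <- clamp(boxes$cx - boxes$w / 2, 0, 1)
  x2 <- clamp(boxes$cx + boxes$w / 2, 0, 1)
  y1 <- clamp(boxes$cy - boxes$h / 2, 0, 1)
  y2 <- clamp(boxes$cy + boxes$h / 2, 0, 1)
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id,
                     (x1 + x2) / 2, (y1 + y2) / 2, x2 - x1, y2 - y1), path)
  invisible(path)
}

# ---- splitting ------------------------------------------------------------

#' Deterministic train/val/test split
#'
#' Shuffles the ids with a seeded generator and apportions split sizes by
#' the largest-remainder rule on `n * ratios`, so the partition is exact
#' (disjoint and exhaustive) and reproducible.
#'
#' @param ids vector of sample identifiers, length at least 3.
#' @param ratios three positive fractions summing to 1 (default 8:1:1).
#' @param seed integer seed.
#' @return a `dataset_split` list with `train`, `val`, `test`, `ratios`,
#'   `seed`.
#' @examples
#' lengths(split_dataset(1:1250, seed = 0)[1:3]) # 1000 125 125
#' @export
split_dataset <- function(ids, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  n <- length(ids)
  if (n < 3) stop("split_dataset: need at least 3 ids")
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stop("split_dataset: ratios must be 3 positive values summing to 1")
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * ratios - sizes
    add <- order(-frac, seq_along(frac))[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  shuffled <- with_seed(seed, sample(ids))
  structure(list(train = shuffled[seq_len(sizes[1])],
                 val = shuffled[sizes[1] + seq_len(sizes[2])],
                 test = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])],
                 ratios = ratios, seed = seed),
            class = "dataset_split")
}

# ---- augmentation ---------------------------------------------------------

#' Default augmentation parameters
#'
#' Rotation up to +/-15 degrees, isotropic scaling 0.8-1.2 about the image
#' center, HSV jitter gains (hue 0.015, saturation 0.7, value 0.4), and a
#' 4-pixel-squared floor on retained box area.
#' @return parameter list for [augment()].
#' @export
augment_params <- function(rotate = 15, scale = c(0.8, 1.2),
                           hsv_gain = c(0.015, 0.7, 0.4), min_area = 4) {
  list(rotate = rotate, scale = scale, hsv_gain = hsv_gain,
       min_area = min_area)
}

hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

hsv_jitter <- function(img, gains) {
  d <- dim(img)
  m <- matrix(img, ncol = 3)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  dh <- stats::runif(1, -1, 1) * gains[1]
  sg <- 1 + stats::runif(1, -1, 1) * gains[2]
  vg <- 1 + stats::runif(1, -1, 1) * gains[3]
  out <- hsv_to_rgb(hsv[, 1] + dh, clamp(hsv[, 2] * sg, 0, 1),
                    clamp(hsv[, 3] * vg, 0, 1))
  array(out, dim = d)
}

#' Augment one labeled image
#'
#' Applies a random rotation and isotropic scale about the image center
#' (gray fill outside the source) and HSV color jitter; boxes are carried
#' through the affine map by re-enclosing their four transformed corners,
#' then clipped, and dropped when the surviving area falls below
#' `min_area` square pixels.  Deterministic under `seed`; label count never
#' increases.
#'
#' @param sample list with `image` (H, W, 3 array) and `boxes` (normalized
#'   YOLO data frame).
#' @param params see [augment_params()].
#' @param seed integer seed.
#' @return augmented sample list.
#' @export
augment <- function(sample, params = augment_params(), seed = 0L) {
  with_seed(seed, {
    theta <- stats::runif(1, -params$rotate, params$rotate) * pi / 180
    sc <- stats::runif(1, params$scale[1], params$scale[2])
    img <- sample$image
    d <- dim(img)
    h <- d[1]; w <- d[2]
    cxc <- (w) / 2; cyc <- (h) / 2
    ct <- cos(theta); st <- sin(theta)
    identity_geom <- (theta == 0 && sc == 1)
    if (!identity_geom) {
      # inverse map output pixel centers back into the source image
      gx <- rep(seq_len(w) - 0.5, each = h) - cxc
      gy <- rep(seq_len(h) - 0.5, times = w) - cyc
      sx <- (ct * gx + st * gy) / sc + cxc
      sy <- (-st * gx + ct * gy) / sc + cyc
      si <- ceiling(sy); sj <- ceiling(sx)
      inside <- si >= 1 & si <= h & sj >= 1 & sj <= w
      si <- clamp(si, 1, h); sj <- clamp(sj, 1, w)
      out <- array(0.5, dim = d)
      pick <- cbind(si, sj)
      for (ch in 1:3) {
        plane <- img[, , ch]
        vals <- plane[pick]
        vals[!inside] <- 0.5
        out[, , ch] <- matrix(vals, nrow = h)
      }
      img <- out
    }
    if (any(params$hsv_gain > 0)) img <- hsv_jitter(img, params$hsv_gain)

    boxes <- sample$boxes
    if (!is.null(boxes) && nrow(boxes) > 0 && !identity_geom) {
      new_rows <- lapply(seq_len(nrow(boxes)), function(i) {
        bx <- boxes[i, ]
        px <- c(bx$cx - bx$w / 2, bx$cx + bx$w / 2,
                bx$cx + bx$w / 2, bx$cx - bx$w / 2) * w
        py <- c(bx$cy - bx$h / 2, bx$cy - bx$h / 2,
                bx$cy + bx$h / 2, bx$cy + bx$h / 2) * h
        # forward map the corners, re-enclose, clip
        tx <- sc * (ct * (px - cxc) - st * (py - cyc)) + cxc
        ty <- sc * (st * (px - cxc) + ct * (py - cyc)) + cyc
        x1 <- clamp(min(tx), 0, w); x2 <- clamp(max(tx), 0, w)
        y1 <- clamp(min(ty), 0, h); y2 <- clamp(max(ty), 0, h)
        if ((x2 - x1) * (y2 - y1) < params$min_area) return(NULL)
        data.frame(class_id = bx$class_id, cx = (x1 + x2) / 2 / w,
                   cy = (y1 + y2) / 2 / h, w = (x2 - x1) / w,
                   h = (y2 - y1) / h)
      })
      new_rows <- new_rows[!vapply(new_rows, is.null, logical(1))]
      boxes <- if (length(new_rows)) do.call(rbind, new_rows)
               else empty_boxes()
    }
    list(image = img, boxes = boxes)
  })
}

# ---- manifest -------------------------------------------------------------

#' Write a dataset manifest
#' @param root dataset root directory.
#' @param names character vector of class names.
#' @param path manifest destination (default `<root>/data.yaml`).
#' @export
write_manifest <- function(root, names, path = file.path(root, "data.yaml")) {
  yaml::write_yaml(list(path = normalizePath(root),
                        train = "images/train", val = "images/val",
                        test = "images/test",
                        names = as.list(names)), path)
  invisible(path)
}

#' Read a dataset manifest
#' @param path manifest YAML file.
#' @return list with `path`, split subdirectories, and `names`.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$path)) y$path <- dirname(normalizePath(path))
  y$names <- unlist(y$names)
  y
}

# image/label path pairs of one split
split_files <- function(manifest, split = "train") {
  imgdir <- file.path(manifest$path, manifest[[split]])
  imgs <- sort(list.files(imgdir, pattern = "\\.ppm$", full.names = TRUE))
  labs <- file.path(gsub("images", "labels", imgdir),
                    sub("\\.ppm$", ".txt", basename(imgs)))
  data.frame(image = imgs, label = labs, stringsAsFactors = FALSE)
}
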