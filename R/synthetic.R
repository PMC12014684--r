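# Synthetic orchard-scene generator.
#
# Renders labeled images that emulate the statistical structure of orchard
# photographs — foliage-textured backgrounds, shaded near-circular fruit
# with hue jitter around orange-red, fruit stacking (clusters), elongated
# branch/leaf occluders, and global lighting variation — so the full
# detection pipeline is exercisable without any external data.  The
# contract is structure, not photorealism: a fruit is a radial-gradient
# disc, an occluder a rotated strip.  A fruit whose visible pixel fraction
# falls below the visibility floor is not labeled (annotation realism).

#' Scene generation parameters
#'
#' @param image_size square image side in pixels.
#' @param n_fruits fruit count, a single count or an inclusive range.
#' @param radius_range fruit radius range in pixels.
#' @param cluster_prob probability that a fruit is placed adjacent to
#'   (stacked on) a previous fruit rather than independently.
#' @param occluder_prob per-fruit probability of drawing a branch/leaf
#'   strip across it.
#' @param max_occlusion_frac cap on the fraction of a fruit an occluder may
#'   cover.
#' @param brightness_range global multiplicative lighting factor range.
#' @param visibility_floor minimum visible fraction for a fruit to be
#'   labeled.
#' @return a `scene_params` list.
#' @export
scene_params <- function(image_size = 256L, n_fruits = c(3L, 8L),
                         radius_range = c(12, 32), cluster_prob = 0.3,
                         occluder_prob = 0.3, max_occlusion_frac = 0.5,
                         brightness_range = c(0.6, 1.3),
                         visibility_floor = 0.25) {
  stopifnot(image_size >= 32,
            all(n_fruits >= 0), radius_range[1] <= radius_range[2],
            cluster_prob >= 0, cluster_prob <= 1,
            occluder_prob >= 0, occluder_prob <= 1,
            max_occlusion_frac >= 0, max_occlusion_frac <= 1,
            brightness_range[1] <= brightness_range[2],
            visibility_floor >= 0, visibility_floor <= 1)
  structure(list(image_size = as.integer(image_size),
                 n_fruits = as.integer(n_fruits),
                 radius_range = radius_range,
                 cluster_prob = cluster_prob,
                 occluder_prob = occluder_prob,
                 max_occlusion_frac = max_occlusion_frac,
                 brightness_range = brightness_range,
                 visibility_floor = visibility_floor),
            class = "scene_params")
}

# low-frequency foliage texture: coarse random green grid, upsampled
foliage_background <- function(size) {
  coarse <- 16L
  base_g <- matrix(stats::runif(coarse^2, 0.30, 0.55), coarse)
  base_r <- matrix(stats::runif(coarse^2, 0.05, 0.22), coarse)
  base_b <- matrix(stats::runif(coarse^2, 0.02, 0.18), coarse)
  idx <- clamp(ceiling(seq_len(size) / size * coarse), 1, coarse)
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- base_r[idx, idx]
  img[, , 2] <- base_g[idx, idx]
  img[, , 3] <- base_b[idx, idx]
  # fine speckle so the texture is not blocky
  img + array(stats::runif(size * size * 3, -0.03, 0.03),
              dim = c(size, size, 3))
}

#' Generate one labeled orchard scene
#'
#' @param params a [scene_params()].
#' @param seed integer seed; the scene is bit-identical under the same
#'   params and seed.
#' @return list with `image` (H, W, 3 array in `[0, 1]`), `boxes`
#'   (normalized YOLO data frame, class 0 = fruit), and `meta` (per-fruit
#'   placement record: center, radius, visible fraction, labeled flag).
#' @export
generate_scene <- function(params = scene_params(), seed = 0L) {
  with_seed(seed, {
    S <- params$image_size
    img <- foliage_background(S)
    n <- if (length(params$n_fruits) > 1)
      sample(params$n_fruits[1]:params$n_fruits[2], 1) else params$n_fruits
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), nrow = S)   # column coord
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), nrow = S)  # row coord
    owner <- matrix(0L, S, S)  # which fruit owns each pixel (topmost)
    meta <- list()
    placed <- 0L
    if (n > 0) for (k in seq_len(n)) {
      r <- stats::runif(1, params$radius_range[1], params$radius_range[2])
      ok <- FALSE
      for (try in 1:25) {
        clustered <- placed > 0 && stats::runif(1) < params$cluster_prob
        if (clustered) {
          # stacked placement: deliberately adjacent / overlapping
          anchor <- meta[[sample(placed, 1)]]
          ang <- stats::runif(1, 0, 2 * pi)
          dd <- stats::runif(1, 0.7, 1.2) * (anchor$r + r) / 2
          cx <- anchor$cx + cos(ang) * dd
          cy <- anchor$cy + sin(ang) * dd
        } else {
          cx <- stats::runif(1, r, S - r)
          cy <- stats::runif(1, r, S - r)
        }
        inside <- cx >= r / 2 && cx <= S - r / 2 &&
          cy >= r / 2 && cy <= S - r / 2
        separate <- clustered || placed == 0 ||
          all(vapply(meta[seq_len(placed)], function(f)
            (f$cx - cx)^2 + (f$cy - cy)^2 >= (f$r + r + 1)^2, logical(1)))
        if (inside && separate) {
          ok <- TRUE
          break
        }
      }
      if (!ok) next
      placed <- placed + 1L
      hue <- stats::runif(1, 0.015, 0.10)  # orange-red band
      sat <- stats::runif(1, 0.75, 0.95)
      dist2 <- (xs - cx)^2 + (ys - cy)^2
      mask <- dist2 <= r^2
      shade <- 1 - 0.55 * sqrt(pmax(dist2, 0)) / r  # radial gradient
      val <- clamp(0.95 * shade, 0, 1)
      rgb <- hsv_to_rgb(rep(hue, sum(mask)), rep(sat, sum(mask)), val[mask])
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- rgb[, ch]
        img[, , ch] <- plane
      }
      owner[mask] <- placed
      meta[[placed]] <- list(cx = cx, cy = cy, r = r, area = sum(mask))
    }
    # occluders: elongated strips in branch/leaf tones across chosen fruits
    if (placed > 0) for (k in seq_len(placed)) {
      if (stats::runif(1) >= params$occluder_prob) next
      f <- meta[[k]]
      frac <- stats::runif(1, 0.1, params$max_occlusion_frac)
      half_w <- f$r * frac            # strip half-width sets coverage
      ang <- stats::runif(1, 0, pi)
      off <- stats::runif(1, -0.3, 0.3) * f$r
      nx <- cos(ang); ny <- sin(ang)
      dsig <- (xs - f$cx) * nx + (ys - f$cy) * ny - off
      along <- -(xs - f$cx) * ny + (ys - f$cy) * nx
      strip <- abs(dsig) <= half_w & abs(along) <= 2.5 * f$r
      branch <- stats::runif(1) < 0.5
      col <- if (branch) c(0.35, 0.22, 0.10) else c(0.13, 0.42, 0.12)
      jit <- stats::runif(3, -0.05, 0.05)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[strip] <- clamp(col[ch] + jit[ch], 0, 1)
        img[, , ch] <- plane
      }
      owner[strip] <- -1L  # occluded: owned by no fruit
    }
    bright <- stats::runif(1, params$brightness_range[1],
                           params$brightness_range[2])
    img <- clamp(img * bright, 0, 1)

    boxes <- empty_boxes()
    if (placed > 0) for (k in seq_len(placed)) {
      f <- meta[[k]]
      vis <- sum(owner == k) / f$area
      meta[[k]]$visible_frac <- vis
      meta[[k]]$labeled <- vis >= params$visibility_floor
      if (!meta[[k]]$labeled) next
      x1 <- max(f$cx - f$r, 0); x2 <- min(f$cx + f$r, S)
      y1 <- max(f$cy - f$r, 0); y2 <- min(f$cy + f$r, S)
      boxes <- rbind(boxes, data.frame(
        class_id = 0L, cx = (x1 + x2) / 2 / S, cy = (y1 + y2) / 2 / S,
        w = (x2 - x1) / S, h = (y2 - y1) / S))
    }
    list(image = img, boxes = boxes, meta = meta)
  })
}

#' Generate a YOLO-layout synthetic dataset
#'
#' Writes `n_images` scenes into `out_dir` under the standard directory
#' layout with a manifest, splitting via [split_dataset()]; per-image seeds
#' are derived from the master seed, so regeneration is byte-identical.
#'
#' @param n_images number of scenes.
#' @param params a [scene_params()].
#' @param out_dir output directory (created if needed).
#' @param ratios train/val/test fractions.
#' @param seed master seed.
#' @return path of the written manifest; attributes carry the split and the
#'   total number of labeled fruits.
#' @export
generate_dataset <- function(n_images, params = scene_params(),
                             out_dir, ratios = c(0.8, 0.1, 0.1),
                             seed = 0L) {
  ids <- seq_len(n_images)
  sp <- split_dataset(ids, ratios, seed)
  for (d in c("images", "labels"))
    for (s in c("train", "val", "test"))
      dir.create(file.path(out_dir, d, s), recursive = TRUE,
                 showWarnings = FALSE)
  seeds <- derive_seeds(seed, n_images, salt = 1L)
  split_of <- character(n_images)
  split_of[sp$train] <- "train"
  split_of[sp$val] <- "val"
  split_of[sp$test] <- "test"
  total_labels <- 0L
  for (i in ids) {
    sc <- generate_scene(params, seeds[i])
    stem <- sprintf("scene_%04d", i)
    write_ppm(sc$image,
              file.path(out_dir, "images", split_of[i],
                        paste0(stem, ".ppm")))
    write_yolo_labels(sc$boxes,
                      file.path(out_dir, "labels", split_of[i],
                                paste0(stem, ".txt")))
    total_labels <- total_labels + nrow(sc$boxes)
  }
  manifest <- write_manifest(out_dir, names = "fruit")
  attr(manifest, "split") <- sp
  attr(manifest, "total_labels") <- total_labels
  manifest
}
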