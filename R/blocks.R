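# Functional forms of the network's building blocks.
#
# These operate on a single feature map — a (channels, height, width) array —
# with explicitly supplied weights and no normalization, so their semantics
# are pure convolution algebra and can be checked against a brute-force
# direct-convolution oracle.  The trainable network modules in layers.R wrap
# the same kernels with batch normalization and learned parameters.

#' Validate a convolution specification
#'
#' Describes the dimensions of one convolution: input spatial size, channel
#' counts, (odd) kernel size, stride, and groups (1 = standard convolution,
#' `in_channels` = depthwise).  Used by the analytic FLOP accounting.
#'
#' @param height,width input spatial size in pixels.
#' @param in_channels,out_channels channel counts.
#' @param kernel odd kernel size in pixels.
#' @param stride positive integer stride.
#' @param groups number of channel groups; `in_channels` must be divisible
#'   by it.
#' @return a `conv_spec` list.
#' @examples
#' conv_spec(8, 8, 4, 8, kernel = 3)
#' @export
conv_spec <- function(height, width, in_channels, out_channels, kernel = 3L,
                      stride = 1L, groups = 1L) {
  vals <- c(height = height, width = width, in_channels = in_channels,
            out_channels = out_channels, kernel = kernel, stride = stride,
            groups = groups)
  if (any(vals < 1) || any(vals != round(vals)))
    stop("conv_spec: all fields must be positive integers")
  if (kernel %% 2 != 1) stop("conv_spec: kernel size must be odd")
  if (in_channels %% groups != 0)
    stop("conv_spec: in_channels must be divisible by groups")
  structure(as.list(vals), class = "conv_spec")
}

#' Configuration of one inverted bottleneck block
#'
#' The block expands channels by `expansion`, filters with a depthwise
#' kernel, and compresses back.  The identity shortcut is active exactly
#' when `stride == 1` and the channel count is unchanged; there is no
#' projection shortcut.
#'
#' @param in_channels,out_channels channel counts.
#' @param expansion positive channel expansion factor e; the expanded width
#'   is `round(e * in_channels)`.
#' @param kernel odd depthwise kernel size.
#' @param stride 1 or 2.
#' @return a `block_config` list with the derived `residual` flag and
#'   `expanded` channel count.
#' @export
block_config <- function(in_channels, out_channels, expansion = 4,
                         kernel = 3L, stride = 1L) {
  if (!(stride %in% c(1, 2))) stop("block_config: stride must be 1 or 2")
  if (expansion <= 0) stop("block_config: expansion must be positive")
  expanded <- max(1L, as.integer(round(expansion * in_channels)))
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 expansion = expansion, kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 expanded = expanded,
                 residual = (stride == 1 && in_channels == out_channels)),
            class = "block_config")
}

check_fmap <- function(x, what = "x") {
  if (length(dim(x)) != 3L)
    stop(what, " must be a (channels, height, width) array")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

conv3 <- function(x, w, stride = 1L, groups = 1L) {
  dim(x) <- c(dim(x), 1L)
  y <- .conv2d_fwd(x, w, NULL, as.integer(stride), as.integer(groups))
  dim(y) <- dim(y)[1:3]
  y
}

as_w4 <- function(w, cout, cpg, k) {
  w <- as.array(w)
  dim(w) <- c(cout, cpg, k, k)
  w
}

#' Depthwise-separable convolution (functional)
#'
#' Applies one K x K kernel per input channel (depthwise stage), then a
#' 1 x 1 cross-channel map (pointwise stage), with "same" padding so the
#' output spatial size is `ceiling(input / stride)`.
#'
#' @param x feature map, a (channels, height, width) array.
#' @param spec a [conv_spec()] whose `in_channels` matches `x`.
#' @param weights list with `depthwise`, an array of dim
#'   `(in_channels, K, K)`, and `pointwise`, a matrix of dim
#'   `(out_channels, in_channels)`.
#' @return a (out_channels, H', W') array.
#' @export
dws_conv <- function(x, spec, weights) {
  check_fmap(x)
  if (dim(x)[1] != spec$in_channels)
    stop("dws_conv: x has ", dim(x)[1], " channels but spec expects ",
         spec$in_channels)
  cin <- spec$in_channels
  k <- spec$kernel
  dw <- as_w4(weights$depthwise, cin, 1L, k)
  y <- conv3(x, dw, stride = spec$stride, groups = cin)
  pw <- as_w4(weights$pointwise, spec$out_channels, cin, 1L)
  conv3(y, pw)
}

#' Inverted bottleneck residual block (functional)
#'
#' Computes pointwise expansion (Hard-Swish), depthwise K x K filtering at
#' the block stride (Hard-Swish), and linear pointwise compression; adds the
#' identity shortcut when the configuration allows it, and finishes with
#' Hard-Swish.
#'
#' @param x feature map (channels, height, width).
#' @param cfg a [block_config()].
#' @param weights list with `expand` (expanded x in matrix), `depthwise`
#'   (expanded x K x K array) and `project` (out x expanded matrix).
#' @return feature map with `cfg$out_channels` channels.
#' @export
invres_block <- function(x, cfg, weights) {
  check_fmap(x)
  if (dim(x)[1] != cfg$in_channels)
    stop("invres_block: x has ", dim(x)[1], " channels but cfg expects ",
         cfg$in_channels)
  ce <- cfg$expanded
  h <- conv3(x, as_w4(weights$expand, ce, cfg$in_channels, 1L))
  h <- hard_swish(h)
  dw <- as_w4(weights$depthwise, ce, 1L, cfg$kernel)
  h <- conv3(h, dw, stride = cfg$stride, groups = ce)
  h <- hard_swish(h)
  y <- conv3(h, as_w4(weights$project, cfg$out_channels, ce, 1L))
  if (cfg$residual) y <- y + x
  hard_swish(y)
}

#' Stack of inverted bottleneck blocks (functional)
#'
#' The first block follows `cfg` (and may change stride or width); the
#' remaining `n_blocks - 1` are residual blocks at stride 1 with equal
#' channels.
#'
#' @param x feature map.
#' @param n_blocks number of blocks, at least 1.
#' @param cfg [block_config()] of the first block.
#' @param weights list of per-block weight lists (see [invres_block()]),
#'   length `n_blocks`.
#' @return feature map with `cfg$out_channels` channels.
#' @export
invres_layer <- function(x, n_blocks, cfg, weights) {
  if (n_blocks < 1) stop("invres_layer: n_blocks must be >= 1")
  if (length(weights) != n_blocks)
    stop("invres_layer: need one weight set per block")
  y <- invres_block(x, cfg, weights[[1]])
  if (n_blocks > 1) {
    cfg_rest <- block_config(cfg$out_channels, cfg$out_channels,
                             cfg$expansion, cfg$kernel, stride = 1L)
    for (i in 2:n_blocks) y <- invres_block(y, cfg_rest, weights[[i]])
  }
  y
}

#' Ghost convolution (functional)
#'
#' Half the output maps come from a standard convolution (the primary half),
#' the other half from a cheap 5 x 5 depthwise transform of the primary
#' maps; the result is their channel concatenation, primary half first.
#'
#' @param x feature map.
#' @param out_channels even number of output channels.
#' @param weights list with `primary`, an array of dim
#'   `(out_channels/2, in_channels, K, K)`, and `cheap`, an array of dim
#'   `(out_channels/2, 5, 5)`.
#' @return feature map with `out_channels` channels.
#' @export
ghost_conv <- function(x, out_channels, weights) {
  check_fmap(x)
  if (out_channels %% 2 != 0)
    stop("ghost_conv: out_channels must be even")
  half <- out_channels %/% 2L
  pw <- as.array(weights$primary)
  k <- dim(pw)[3]
  p <- conv3(x, as_w4(pw, half, dim(x)[1], k))
  cheap <- conv3(p, as_w4(weights$cheap, half, 1L, 5L), groups = half)
  out <- array(0, dim = c(out_channels, dim(p)[2], dim(p)[3]))
  out[seq_len(half), , ] <- p
  out[half + seq_len(half), , ] <- cheap
  out
}
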