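# Minimal reverse-mode autodiff over plain R arrays.
#
# Tensors flowing through the network are 4-D arrays with dim (C, H, W, N).
# A forward pass records every operation on a tape; ag_backward() walks the
# tape in reverse, accumulating gradients into leaf parameters.  This is all
# the machinery the detector needs: convolution (C++ kernels), batch
# normalization, Hard-Swish, addition, channel concatenation, nearest
# upsampling, and normalized weighted fusion.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

#' @keywords internal
ag_tape_start <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$tape_len <- 0L
  invisible(NULL)
}

ag_tape_stop <- function() {
  .ag$tape <- NULL
  .ag$tape_len <- 0L
  invisible(NULL)
}

ag_recording <- function() !is.null(.ag$tape)

ag_record <- function(node) {
  n <- .ag$tape_len + 1L
  if (n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
  .ag$tape[[n]] <- node
  .ag$tape_len <- n
  node
}

#' Create an autodiff node
#'
#' @param value numeric array (or vector) held by the node.
#' @param parents list of parent nodes the value was computed from.
#' @param backward function(node) that reads `node$grad` and adds the
#'   corresponding contributions into each parent's `grad`.
#' @param is_param mark the node as a trainable leaf.
#' @keywords internal
ag_node <- function(value, parents = list(), backward = NULL,
                    is_param = FALSE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$is_param <- is_param
  class(node) <- "ag_node"
  if (!is_param && ag_recording() && (length(parents) > 0L)) ag_record(node)
  node
}

ag_param <- function(value) ag_node(value, is_param = TRUE)

ag_accum <- function(node, g) {
  if (!inherits(node, "ag_node")) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Reverse sweep from a node
#'
#' Seeds `node$grad` with `seed` (defaults to ones) and propagates gradients
#' back through every recorded operation.  Multiple seeds may be planted on
#' different nodes before a single sweep by passing `sweep_only = TRUE`
#' seeds via ag_accum() and then calling `ag_backward(NULL)`.
#' @keywords internal
ag_backward <- function(node = NULL, seed = NULL) {
  if (!is.null(node)) {
    if (is.null(seed)) seed <- array(1, dim = dim(node$value))
    ag_accum(node, seed)
  }
  if (.ag$tape_len == 0L) return(invisible(NULL))
  for (i in rev(seq_len(.ag$tape_len))) {
    nd <- .ag$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("tensor must be an array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("tensor must have 3 or 4 dims (C,H,W[,N])")
  x
}

# ---- operations -----------------------------------------------------------

ag_conv2d <- function(x, w, b = NULL, stride = 1L, groups = 1L) {
  xv <- ag_value(x)
  bv <- if (is.null(b)) NULL else ag_value(b)
  y <- .conv2d_fwd(xv, ag_value(w), bv, as.integer(stride),
                   as.integer(groups))
  parents <- list(x = x, w = w)
  if (!is.null(b)) parents$b <- b
  ag_node(y, parents, backward = function(node) {
    gr <- .conv2d_bwd(ag_value(node$parents$x), ag_value(node$parents$w),
                      node$grad, as.integer(stride), as.integer(groups),
                      !is.null(node$parents$b))
    ag_accum(node$parents$x, gr$gx)
    ag_accum(node$parents$w, gr$gw)
    if (!is.null(node$parents$b)) ag_accum(node$parents$b, gr$gb)
  })
}

# Batch normalization over (H, W, N) per channel.  `state` is an environment
# carrying running_mean / running_var, updated in training mode only.
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- ag_value(x)
  d <- dim(xv)
  C <- d[1]
  m <- prod(d[-1])
  if (training) {
    st <- .bn_stats(xv, C)
    mu <- st$mean
    v <- st$var
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    unb <- if (m > 1) m / (m - 1) else 1
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * v * unb
  } else {
    mu <- state$running_mean
    v <- state$running_var
  }
  istd <- 1 / sqrt(v + eps)
  y <- .bn_fwd(xv, ag_value(gamma), ag_value(beta), mu, istd)
  ag_node(y, list(x = x, gamma = gamma, beta = beta),
          backward = function(node) {
    gr <- .bn_bwd(ag_value(node$parents$x), node$grad,
                  ag_value(node$parents$gamma), mu, istd, training)
    ag_accum(node$parents$gamma, gr$ggamma)
    ag_accum(node$parents$beta, gr$gbeta)
    ag_accum(node$parents$x, gr$gx)
  })
}

#' Hard-Swish activation
#'
#' Elementwise `x * min(max(x + 3, 0), 6) / 6`: identity for x >= 3, zero
#' for x <= -3, with global minimum -0.375 at x = -1.5.  Works on plain
#' numerics, arrays, and autodiff nodes.
#'
#' @param x numeric vector/array or an internal autodiff node.
#' @return same shape as the input.
#' @examples
#' hard_swish(c(-4, -3, -1.5, 0, 1, 3, 5))
#' @export
hard_swish <- function(x) {
  if (inherits(x, "ag_node")) return(ag_hardswish(x))
  if (!all(is.finite(x))) stop("hard_swish: input contains non-finite values")
  x * pmin(pmax(x + 3, 0), 6) / 6
}

ag_hardswish <- function(x) {
  xv <- ag_value(x)
  ag_node(.hswish_fwd(xv), list(x = x), backward = function(node) {
    ag_accum(node$parents$x, .hswish_bwd(ag_value(node$parents$x), node$grad))
  })
}

ag_add <- function(a, b) {
  y <- ag_value(a) + ag_value(b)
  ag_node(y, list(a = a, b = b), backward = function(node) {
    ag_accum(node$parents$a, node$grad)
    ag_accum(node$parents$b, node$grad)
  })
}

ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  Cout <- sum(cs)
  y <- array(0, dim = c(Cout, d1[2], d1[3], d1[4]))
  at <- 0L
  for (i in seq_along(vals)) {
    y[at + seq_len(cs[i]), , , ] <- vals[[i]]
    at <- at + cs[i]
  }
  ag_node(y, xs, backward = function(node) {
    at <- 0L
    for (i in seq_along(node$parents)) {
      gi <- node$grad[at + seq_len(cs[i]), , , , drop = FALSE]
      ag_accum(node$parents[[i]], gi)
      at <- at + cs[i]
    }
  })
}

# Nearest-neighbour 2x upsampling; backward is 2x2 sum pooling.
ag_upsample2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv)
  ih <- rep(seq_len(d[2]), each = 2)
  iw <- rep(seq_len(d[3]), each = 2)
  y <- xv[, ih, iw, , drop = FALSE]
  ag_node(y, list(x = x), backward = function(node) {
    g <- node$grad
    o1 <- seq(1, 2 * d[2], by = 2)
    o2 <- seq(1, 2 * d[3], by = 2)
    gx <- g[, o1, o2, , drop = FALSE] + g[, o1 + 1, o2, , drop = FALSE] +
      g[, o1, o2 + 1, , drop = FALSE] + g[, o1 + 1, o2 + 1, , drop = FALSE]
    ag_accum(node$parents$x, gx)
  })
}

# Fast normalized fusion: O = sum_i relu(w_i) X_i / (sum_j relu(w_j) + eps).
ag_wfuse <- function(xs, w, eps = 1e-4) {
  wv <- ag_value(w)
  rw <- pmax(wv, 0)
  S <- sum(rw) + eps
  vals <- lapply(xs, ag_value)
  y <- Reduce(`+`, Map(function(v, a) a * v, vals, rw / S))
  parents <- c(xs, list(w = w))
  nx <- length(xs)
  ag_node(y, parents, backward = function(node) {
    g <- node$grad
    gw <- numeric(length(wv))
    for (i in seq_len(nx)) {
      ag_accum(node$parents[[i]], g * (rw[i] / S))
      gw[i] <- if (wv[i] > 0) sum(g * (vals[[i]] - y)) / S else 0
    }
    ag_accum(node$parents$w, gw)
  })
}
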