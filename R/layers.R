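# Network building blocks as stateful modules.
#
# A module is an environment holding parameter nodes (`params`), batch-norm
# state environments (`bn`), submodules (`sub`), a `forward(x, training)`
# closure, and a `complexity(hw)` closure used by the analytic FLOP walker.
# Convolution weights use Kaiming fan-out initialization; normalization
# scale starts at one, shift at zero, so a freshly built block with zeroed
# conv weights reduces to its activation.

new_module <- function(kind) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$params <- list()
  m$bn <- list()
  m$sub <- list()
  class(m) <- "od_module"
  m
}

kaiming_conv <- function(cout, cpg, k, fan_out) {
  array(stats::rnorm(cout * cpg * k * k, sd = sqrt(2 / fan_out)),
        dim = c(cout, cpg, k, k))
}

new_bn_state <- function(C) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  st
}

conv_out_hw <- function(hw, stride) as.integer(ceiling(hw / stride))

cx_entry <- function(name, params, flops) {
  data.frame(layer = name, params = as.numeric(params),
             flops = as.numeric(flops), stringsAsFactors = FALSE)
}

conv_cx <- function(name, hw, cin, cout, k, stride, groups, bias) {
  out <- conv_out_hw(hw, stride)
  flops <- prod(out) * (cin / groups) * cout * k^2
  params <- cout * (cin / groups) * k^2 + if (bias) cout else 0
  list(df = cx_entry(name, params, flops), hw = out)
}

# plain convolution (optionally with bias); the only unit owning conv weights
od_conv <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                    bias = TRUE, name = "conv") {
  stopifnot(cin %% groups == 0, cout %% groups == 0, k %% 2 == 1)
  m <- new_module("conv")
  m$meta <- list(cin = cin, cout = cout, k = k, stride = stride,
                 groups = groups, bias = bias, name = name)
  m$params$w <- ag_param(kaiming_conv(cout, cin %/% groups, k,
                                      fan_out = k * k * cout / groups))
  if (bias) m$params$b <- ag_param(numeric(cout))
  m$forward <- function(x, training = FALSE)
    ag_conv2d(x, m$params$w, m$params$b, stride = stride, groups = groups)
  m$complexity <- function(hw)
    conv_cx(name, hw, cin, cout, k, stride, groups, bias)
  m
}

act_fn <- function(act) {
  switch(act,
         hswish = ag_hardswish,
         linear = identity,
         stop("unknown activation: ", act))
}

# conv -> batch norm -> activation
od_conv_bn <- function(cin, cout, k = 1L, stride = 1L, groups = 1L,
                       act = "hswish", name = "conv_bn") {
  m <- new_module("conv_bn")
  m$sub$conv <- od_conv(cin, cout, k, stride, groups, bias = FALSE,
                        name = name)
  m$params$gamma <- ag_param(rep(1, cout))
  m$params$beta <- ag_param(numeric(cout))
  m$bn$state <- new_bn_state(cout)
  a <- act_fn(act)
  m$forward <- function(x, training = FALSE) {
    y <- m$sub$conv$forward(x, training)
    y <- ag_batchnorm(y, m$params$gamma, m$params$beta, m$bn$state,
                      training = training)
    a(y)
  }
  m$complexity <- function(hw) {
    cc <- m$sub$conv$complexity(hw)
    cc$df <- rbind(cc$df, cx_entry(paste0(name, ".bn"), 2 * cout, 0))
    cc
  }
  m
}

# depthwise separable convolution: depthwise KxK then pointwise 1x1,
# each followed by normalization and activation
od_dws <- function(cin, cout, k = 3L, stride = 1L, act = "hswish",
                   name = "dws") {
  m <- new_module("dws")
  m$sub$dw <- od_conv_bn(cin, cin, k, stride, groups = cin, act = act,
                         name = paste0(name, ".dw"))
  m$sub$pw <- od_conv_bn(cin, cout, 1L, 1L, act = act,
                         name = paste0(name, ".pw"))
  m$forward <- function(x, training = FALSE)
    m$sub$pw$forward(m$sub$dw$forward(x, training), training)
  m$complexity <- function(hw) {
    c1 <- m$sub$dw$complexity(hw)
    c2 <- m$sub$pw$complexity(c1$hw)
    list(df = rbind(c1$df, c2$df), hw = c2$hw)
  }
  m
}

# Inverted bottleneck residual block: pointwise expand (Hard-Swish),
# depthwise KxK at the block stride (Hard-Swish), pointwise compress
# (linear), identity shortcut when stride 1 and equal channels, Hard-Swish
# after the addition.
od_invres_block <- function(cin, cout, expansion = 4, k = 3L, stride = 1L,
                            name = "block") {
  stopifnot(stride %in% c(1L, 2L))
  cexp <- max(1L, as.integer(round(expansion * cin)))
  m <- new_module("invres_block")
  m$meta <- list(cin = cin, cout = cout, cexp = cexp, k = k, stride = stride,
                 residual = (stride == 1L && cin == cout))
  m$sub$expand <- od_conv_bn(cin, cexp, 1L, 1L, act = "hswish",
                             name = paste0(name, ".expand"))
  m$sub$depth <- od_conv_bn(cexp, cexp, k, stride, groups = cexp,
                            act = "hswish", name = paste0(name, ".depth"))
  m$sub$project <- od_conv_bn(cexp, cout, 1L, 1L, act = "linear",
                              name = paste0(name, ".project"))
  m$forward <- function(x, training = FALSE) {
    y <- m$sub$project$forward(
      m$sub$depth$forward(
        m$sub$expand$forward(x, training), training), training)
    if (m$meta$residual) y <- ag_add(y, x)
    ag_hardswish(y)
  }
  m$complexity <- function(hw) {
    c1 <- m$sub$expand$complexity(hw)
    c2 <- m$sub$depth$complexity(c1$hw)
    c3 <- m$sub$project$complexity(c2$hw)
    list(df = rbind(c1$df, c2$df, c3$df), hw = c3$hw)
  }
  m
}

# Stack of inverted bottleneck blocks; the first may change channels and
# stride, the rest are residual.
od_invres_layer <- function(cin, cout, n_blocks, expansion = 4, k = 3L,
                            stride = 1L, name = "layer") {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  m <- new_module("invres_layer")
  m$sub$b1 <- od_invres_block(cin, cout, expansion, k, stride,
                              name = paste0(name, ".b1"))
  if (n_blocks > 1) {
    for (i in 2:n_blocks)
      m$sub[[paste0("b", i)]] <-
        od_invres_block(cout, cout, expansion, k, 1L,
                        name = paste0(name, ".b", i))
  }
  m$forward <- function(x, training = FALSE) {
    for (b in m$sub) x <- b$forward(x, training)
    x
  }
  m$complexity <- function(hw) {
    dfs <- list()
    for (b in m$sub) {
      cc <- b$complexity(hw)
      dfs[[length(dfs) + 1L]] <- cc$df
      hw <- cc$hw
    }
    list(df = do.call(rbind, dfs), hw = hw)
  }
  m
}

# Ghost convolution: primary half by standard convolution, cheap half by a
# 5x5 depthwise transform of the primary maps, concatenated primary-first.
od_ghost <- function(cin, cout, k = 1L, stride = 1L, act = "hswish",
                     name = "ghost") {
  if (cout %% 2 != 0) stop("ghost convolution needs an even out_channels")
  half <- cout %/% 2L
  m <- new_module("ghost")
  m$sub$primary <- od_conv_bn(cin, half, k, stride, act = act,
                              name = paste0(name, ".primary"))
  m$sub$cheap <- od_conv_bn(half, half, 5L, 1L, groups = half, act = act,
                            name = paste0(name, ".cheap"))
  m$forward <- function(x, training = FALSE) {
    p <- m$sub$primary$forward(x, training)
    ch <- m$sub$cheap$forward(p, training)
    ag_concat_c(list(p, ch))
  }
  m$complexity <- function(hw) {
    c1 <- m$sub$primary$complexity(hw)
    c2 <- m$sub$cheap$complexity(c1$hw)
    list(df = rbind(c1$df, c2$df), hw = c2$hw)
  }
  m
}

od_sequential <- function(mods, name = "seq") {
  m <- new_module("sequential")
  if (is.null(names(mods))) names(mods) <- paste0("s", seq_along(mods))
  m$sub <- mods
  m$forward <- function(x, training = FALSE) {
    for (s in m$sub) x <- s$forward(x, training)
    x
  }
  m$complexity <- function(hw) {
    dfs <- list()
    for (s in m$sub) {
      cc <- s$complexity(hw)
      dfs[[length(dfs) + 1L]] <- cc$df
      hw <- cc$hw
    }
    list(df = do.call(rbind, dfs), hw = hw)
  }
  m
}

# ---- parameter / state traversal ------------------------------------------

#' @keywords internal
od_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params))
    out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$sub))
    out <- c(out, od_parameters(m$sub[[nm]], paste0(prefix, nm, ".")))
  out
}

od_bn_states <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$bn))
    out[[paste0(prefix, nm)]] <- m$bn[[nm]]
  for (nm in names(m$sub))
    out <- c(out, od_bn_states(m$sub[[nm]], paste0(prefix, nm, ".")))
  out
}

od_num_params <- function(m) {
  sum(vapply(od_parameters(m), function(p) length(p$value), numeric(1)))
}
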