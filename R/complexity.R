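# Analytic FLOP and parameter accounting.
#
# FLOPs are counted as multiply-accumulates over the *output* spatial grid
# (the standard convention; identical to counting over the input grid at
# stride 1).  Bias, normalization, and activation are excluded, matching the
# magnitude convention of detection-model GFLOP tables.

spec_out_hw <- function(spec) {
  c(conv_out_hw(spec$height, spec$stride), conv_out_hw(spec$width, spec$stride))
}

#' FLOPs of a standard convolution
#'
#' `H' x W' x Cin x Cout x K^2` multiply-accumulates, where `H', W'` are the
#' output spatial dimensions.
#'
#' @param spec a [conv_spec()] with `groups = 1`.
#' @return multiply-accumulate count.
#' @examples
#' flops_standard_conv(conv_spec(8, 8, 4, 8, kernel = 3)) # 18432
#' @export
flops_standard_conv <- function(spec) {
  if (spec$groups != 1)
    stop("flops_standard_conv: spec must have groups = 1")
  hw <- spec_out_hw(spec)
  hw[1] * hw[2] * spec$in_channels * spec$out_channels * spec$kernel^2
}

#' FLOPs of a depthwise-separable convolution
#'
#' Depthwise stage `H' x W' x Cin x K^2`, pointwise stage
#' `H' x W' x Cin x Cout`, and their sum.  Relative to a standard
#' convolution of the same spec this saves a factor of about
#' `1/Cout + 1/K^2`.
#'
#' @param spec a [conv_spec()].
#' @return list with `dw`, `pw`, and `total` multiply-accumulate counts.
#' @examples
#' flops_depthwise_separable(conv_spec(8, 8, 4, 8, kernel = 3))
#' @export
flops_depthwise_separable <- function(spec) {
  hw <- spec_out_hw(spec)
  a <- hw[1] * hw[2]
  dw <- a * spec$in_channels * spec$kernel^2
  pw <- a * spec$in_channels * spec$out_channels
  list(dw = dw, pw = pw, total = dw + pw)
}

#' Analytic complexity report for a model
#'
#' Walks every convolution and normalization unit of an assembled detector,
#' counting parameters exactly and FLOPs per the convolution-class formulas
#' (standard, depthwise, pointwise, grouped), at the given square input
#' size.
#'
#' @param model a model built by [build_model()].
#' @param input_size input image side length in pixels.
#' @return a `complexity_report` list: `per_layer` data frame
#'   (layer, params, flops), `total_params`, `total_flops`, `params_M`,
#'   `gflops`, `input_size`.
#' @export
model_complexity <- function(model, input_size = 640L) {
  cc <- model$complexity(c(input_size, input_size))
  df <- cc$df
  total_params <- sum(df$params)
  total_flops <- sum(df$flops)
  structure(list(per_layer = df,
                 total_params = total_params,
                 total_flops = total_flops,
                 params_M = round(total_params / 1e6, 3),
                 gflops = round(total_flops / 1e9, 3),
                 input_size = input_size),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity report @ %dx%d\n", x$input_size, x$input_size))
  cat(sprintf("  layers:     %d\n", nrow(x$per_layer)))
  cat(sprintf("  parameters: %s (%.3f M)\n",
              format(x$total_params, big.mark = ","), x$params_M))
  cat(sprintf("  FLOPs:      %s (%.3f GFLOPs)\n",
              format(x$total_flops, big.mark = ","), x$gflops))
  invisible(x)
}

#' Relative change between two scalar measurements
#'
#' Signed percent change `100 * (after - before) / before`, rounded to three
#' decimals — the arithmetic behind ablation-table statements such as "the
#' GFLOPs were reduced by 35.129%" (42.7 -> 27.7).
#'
#' @param before,after positive baseline value and new value.
#' @return signed percent, 3 decimals.
#' @examples
#' relative_change(42.7, 27.7)   # -35.129
#' relative_change(0.931, 0.964) # +3.545
#' @export
relative_change <- function(before, after) {
  if (!is.finite(before) || before <= 0)
    stop("relative_change: 'before' must be a positive number")
  round(100 * (after - before) / before, 3)
}
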