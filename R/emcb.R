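# Efficient Mapping Convolutional Block and the 5-layer decoder.
#
# EMCB: a 3x3 convolution halves the channel count (F1), a depthwise
# "mapping" convolution expands it back by concatenation (F2), a per-channel
# gate F3 in (0,1) — global average pool, cross-channel 1-D convolution of
# kernel k(C), sigmoid — rescales F2, and a pointwise projection of the
# input is added residually: Fout = F2 * F3 + PConv(Fin).

#' Adaptive ECA kernel size
#'
#' `k = ceil(log2(C)) + 1`, raised to the next odd integer when even so the
#' 1-D convolution can be symmetrically padded, with a floor of 3.
#'
#' @param C channel count (>= 1)
#' @return odd integer kernel size
#' @export
eca_kernel_size <- function(C) {
  if (!is.numeric(C) || length(C) != 1L || C < 1)
    stop("C must be a positive integer")
  k <- as.integer(ceiling(log2(C))) + 1L
  if (k %% 2L == 0L) k <- k + 1L
  max(k, 3L)
}

#' Efficient Mapping Convolutional Block
#'
#' @param in_channels,out_channels widths; `out_channels` must be even
#' @return a module; apply with [forward()]
#' @export
emcb <- function(in_channels, out_channels) {
  if (out_channels %% 2L != 0L) stop("out_channels must be even")
  half <- out_channels %/% 2L
  k <- eca_kernel_size(out_channels)
  ch <- list(
    f1 = layer_conv_bn(in_channels, half, 3L, act = TRUE),
    dconv = layer_dw_bn(half, 3L),
    pconv = layer_conv_bn(in_channels, out_channels, 1L))
  params <- list(eca = new_param(stats::rnorm(k, sd = sqrt(2 / k))))
  mk_module(function(x, training = FALSE) {
    f1 <- ch$f1$forward(x, training)
    f2 <- op_concat_c(f1, ch$dconv$forward(f1, training))
    gate <- op_sigmoid(op_conv1d_c(op_gap(f2), params$eca))
    op_add(op_mul_cvec(f2, gate), ch$pconv$forward(x, training))
  }, params = params, children = ch)
}

# plain double 3x3 conv block, the EMCB ablation replacement
double_conv <- function(in_channels, out_channels) {
  ch <- list(c1 = layer_conv_bn(in_channels, out_channels, 3L, act = TRUE),
             c2 = layer_conv_bn(out_channels, out_channels, 3L, act = TRUE))
  mk_module(function(x, training = FALSE)
    ch$c2$forward(ch$c1$forward(x, training), training), children = ch)
}

#' Build the 5-layer decoder
#'
#' Each layer upsamples x2 (bilinear) and applies an EMCB; after layers 1-4
#' the output is concatenated with the matching skip feature. For a 256x256
#' input the EMCB in/out channel trace is 160/112, 224/40, 80/24, 48/16,
#' 32/8 at sizes 16, 32, 64, 128, 256, and a final 1x1 convolution maps the
#' 8 channels to `num_classes` logits.
#'
#' @param num_classes K
#' @param skip_channels encoder stage widths (stages 1..4 skips + deepest)
#' @param use_emcb replace EMCBs by plain double-conv blocks when FALSE
#' @export
decoder_build <- function(num_classes, skip_channels = c(16L, 24L, 40L, 112L, 160L),
                          use_emcb = TRUE) {
  sk <- skip_channels
  # channel trace forced by concatenation: up(out_i) || skip
  dout <- c(112L, 40L, 24L, 16L, 8L)
  din <- c(sk[5], dout[1] + sk[4], dout[2] + sk[3], dout[3] + sk[2], dout[4] + sk[1])
  blk <- if (use_emcb) emcb else double_conv
  ch <- list()
  for (i in 1:5) ch[[sprintf("d%d", i)]] <- blk(din[i], dout[i])
  ch$head <- layer_conv_bn(dout[5], as.integer(num_classes), 1L, bn = FALSE,
                           bias = TRUE)
  mk_module(function(feats, training = FALSE) {
    if (length(feats) != 5L) stop("decoder expects 5 encoder features")
    y <- feats[[5]]
    for (i in 1:5) {
      d <- dim(y$v)
      y <- op_resize_bilinear(y, d[1] * 2L, d[2] * 2L)
      y <- ch[[sprintf("d%d", i)]]$forward(y, training)
      if (i < 5L) y <- op_concat_c(y, feats[[5L - i]])
    }
    ch$head$forward(y, training)
  }, children = ch)
}

#' Run the decoder on a feature pyramid
#' @param decoder a [decoder_build()] module
#' @param features list of 5 arrays from [encode()] (optionally after GSCA)
#' @return logits array `(H, W, K, B)`
#' @export
decode <- function(decoder, features) {
  decoder$forward(lapply(features, node), training = FALSE)$v
}
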