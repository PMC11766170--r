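# Global Spatial-Channel Attention.
#
# Channel branch: a 1x1 convolution scores every pixel, a spatial softmax
# turns the scores into pooling weights, and the weighted sum of the input
# yields a global context vector (C x 1 x 1). Two 1x1 convolutions with a
# layer normalisation in between re-excite the context into E4. Spatial
# branch: the softmax of E4 over channels weights the input's channel rows,
# producing a per-pixel score map whose spatial softmax is E6. The output
# adds both branches residually: Eout = Ein + E4 + E6 (E4 broadcast over
# pixels, E6 over channels).

#' Global Spatial-Channel Attention block
#'
#' @param channels input channel count C
#' @param hidden width of the two-layer excitation (default `max(C/4, 4)`)
#' @return a module; apply with [forward()]
#' @export
gsca_block <- function(channels, hidden = max(channels %/% 4L, 4L)) {
  ch <- list(
    logit = layer_conv_bn(channels, 1L, 1L, bn = FALSE, bias = TRUE),
    fc1 = layer_linear(channels, hidden))
  ch$fc2 <- layer_linear(hidden, channels)
  params <- list(ln_g = new_param(rep(1, hidden)), ln_b = new_param(numeric(hidden)))
  m <- mk_module(function(x, training = FALSE) {
    w <- op_softmax_hw(ch$logit$forward(x, training))          # E2: HW weights
    ctx <- op_spatial_weighted_sum(x, w)                       # E3: C x 1 x 1
    e4 <- ch$fc2$forward(op_ln_c(ch$fc1$forward(ctx, training),
                                 params$ln_g, params$ln_b), training)
    a <- op_softmax_c(e4)                                      # channel weights
    cmap <- op_channel_weighted_sum(x, a)                      # c-row: 1 x HW
    e6 <- op_softmax_hw(cmap)
    op_add_smap(op_add_cvec(x, e4), e6)
  }, params = params, children = ch)
  m$channels <- channels
  m
}

#' Spatial context weights (E2)
#'
#' Softmax over the HW positions of a 1x1-convolution response; weights are
#' non-negative and sum to 1 per sample.
#'
#' @param block a [gsca_block()]
#' @param x input array `(H, W, C, B)`
#' @return array `(H, W, 1, B)`
#' @export
spatial_context_weights <- function(block, x) {
  forward_sub(block, x, function(ch, params, xn, training)
    op_softmax_hw(ch$logit$forward(xn, training)))
}

#' Global context vector (E3)
#' @param x input array `(H, W, C, B)`
#' @param weights spatial weights `(H, W, 1, B)` from
#'   [spatial_context_weights()]
#' @return array `(1, 1, C, B)`: per-channel weighted sum over pixels
#' @export
global_context <- function(x, weights) {
  if (!all(dim(weights) == c(dim(x)[1], dim(x)[2], 1L, dim(x)[4])))
    stop("weights shape does not match input")
  op_spatial_weighted_sum(node(x), node(weights))$v
}

#' Channel excitation (E3 -> E4)
#' @param block a [gsca_block()]
#' @param e3 context vector `(1, 1, C, B)`
#' @export
channel_excitation <- function(block, e3) {
  forward_sub(block, e3, function(ch, params, xn, training)
    ch$fc2$forward(op_ln_c(ch$fc1$forward(xn, training),
                           params$ln_g, params$ln_b), training))
}

#' Spatial reweighting map (E6)
#'
#' Channel-softmax of E4 weights the channel rows of the input; the spatial
#' softmax of the resulting per-pixel scores is E6 (sums to 1 over HW).
#'
#' @param x input array `(H, W, C, B)`
#' @param e4 excitation vector `(1, 1, C, B)` matching `x`'s channels
#' @return array `(H, W, 1, B)`
#' @export
spatial_reweight <- function(x, e4) {
  if (dim(e4)[3] != dim(x)[3]) stop("channel count of e4 does not match input")
  a <- op_softmax_c(node(e4))
  op_softmax_hw(op_channel_weighted_sum(node(x), a))$v
}

forward_sub <- function(block, x, f, training = FALSE) {
  f(block$children, block$params, node(x), training)$v
}
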