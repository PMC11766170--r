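# Ghost-bottleneck discriminator: scores whether a K-channel mask (one-hot
# ground truth or generated probability map) is genuine. Input convolution
# adapted to K channels, three stride-2 ghost bottlenecks, global average
# pooling, a linear head and a sigmoid.

#' Build the mask discriminator
#'
#' @param num_classes channel count K of the scored masks
#' @param widths channel widths of the three ghost stages
#' @param expansion hidden-width expansion factor
#' @param seed optional local RNG seed for reproducible initial weights
#' @return a `ghost_discriminator` module
#' @export
build_discriminator <- function(num_classes = 5L, widths = c(24L, 40L, 80L),
                                expansion = 3, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  ch <- list(stem = layer_conv_bn(as.integer(num_classes), 16L, 3L, stride = 2L,
                                  act = TRUE))
  cin <- 16L
  for (i in seq_along(widths)) {
    hid <- round_mult4(expansion * cin)
    ch[[sprintf("b%d", i)]] <- ghost_bottleneck(cin, hid, widths[i], stride = 2L)
    cin <- widths[i]
  }
  # conv-BN-ReLU neck before pooling: without the ReLU, train-mode batch
  # norm pins every channel's batch mean, collapsing the pooled score
  ch$neck <- layer_conv_bn(cin, 2L * cin, 1L, act = TRUE)
  ch$head <- layer_linear(2L * cin, 1L)
  nb <- length(widths)
  m <- mk_module(function(x, training = FALSE) {
    y <- ch$stem$forward(x, training)
    for (i in seq_len(nb)) y <- ch[[sprintf("b%d", i)]]$forward(y, training)
    op_sigmoid(ch$head$forward(op_gap(ch$neck$forward(y, training)), training))
  }, children = ch)
  m$num_classes <- as.integer(num_classes)
  class(m) <- c("ghost_discriminator", class(m))
  m
}

#' Score masks with the discriminator
#'
#' @param disc a [build_discriminator()] module
#' @param mask_probs array `(H, W, K, B)` of class probabilities or one-hot
#'   ground truth
#' @param training batch-norm mode
#' @return numeric vector of B scores, each strictly in (0, 1)
#' @export
discriminate <- function(disc, mask_probs, training = FALSE) {
  d <- dim(mask_probs)
  if (is.null(d) || length(d) != 4L || d[3] != disc$num_classes)
    stop("expected a (H, W, ", disc$num_classes, ", B) mask array")
  as.numeric(disc$forward(node(mask_probs), training = training)$v)
}

#' One-hot encoding of a label mask
#' @param labels integer array `(H, W, B)`, values in `[0, K)`
#' @param K class count
#' @return array `(H, W, K, B)`
#' @export
one_hot_mask <- function(labels, K) {
  d <- dim(labels)
  if (length(d) == 2L) { d <- c(d, 1L); dim(labels) <- d }
  out <- array(0, c(d[1], d[2], K, d[3]))
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) stop("labels must lie in [0, K)")
  pix <- d[1] * d[2]
  for (b in seq_len(d[3])) {
    lb <- lab[(b - 1L) * pix + seq_len(pix)]
    idx <- seq_len(pix) + lb * pix + (b - 1L) * pix * K
    out[idx] <- 1
  }
  out
}
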