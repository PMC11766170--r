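# Training losses. The generator minimises L_total = L_sup + lambda * L_adv,
# where L_sup is a pixel cross-entropy and/or a soft multi-class Dice loss on
# the predicted class probabilities and L_adv = -E[log D(f(x))] rewards
# probability maps the discriminator scores as genuine. The discriminator is
# trained with binary cross-entropy (real masks -> 1, generated -> 0).
# All log terms clamp probabilities at .eps_prob to stay finite.

.eps_prob <- 1e-7

clamp01 <- function(p) pmin(pmax(p, .eps_prob), 1)

# -- differentiable scalar ops ----------------------------------------------

op_ce_loss <- function(probs, labels) {
  d <- dims4(probs$v); K <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) stop("labels must lie in [0, K)")
  npix <- d[1] * d[2] * d[4]
  # linear index of the true-class probability of every pixel
  pix <- seq_len(d[1] * d[2])
  idx <- integer(npix)
  off_b <- (seq_len(d[4]) - 1L) * d[1] * d[2] * K
  labm <- matrix(lab, d[1] * d[2], d[4])
  for (b in seq_len(d[4]))
    idx[(b - 1L) * length(pix) + pix] <- pix + labm[, b] * d[1] * d[2] + off_b[b]
  pt <- probs$v[idx]
  v <- -mean(log(clamp01(pt)))
  pl <- probs
  node(v, parents = list(pl), bk = function(n) {
    if (!needs_grad(pl)) return(invisible(NULL))
    g <- array(0, d)
    live <- pt > .eps_prob
    g[idx[live]] <- -n$g / (npix * pt[live])
    accum(pl, g)
  })
}

op_dice_loss <- function(probs, labels, smooth = 1e-6) {
  d <- dims4(probs$v); K <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= K)) stop("labels must lie in [0, K)")
  if (K < 2L) stop("dice loss needs at least one foreground class")
  HW <- d[1] * d[2]; B <- d[4]
  P <- array(probs$v, c(HW, K, B))
  labm <- matrix(lab, HW, B)
  num <- den <- dice <- numeric(K - 1L)
  Y <- array(0, c(HW, K - 1L, B))
  for (k in seq_len(K - 1L)) {
    Y[, k, ] <- (labm == k) * 1
    num[k] <- 2 * sum(P[, k + 1L, ] * Y[, k, ]) + smooth
    den[k] <- sum(P[, k + 1L, ]) + sum(Y[, k, ]) + smooth
    dice[k] <- num[k] / den[k]
  }
  v <- 1 - mean(dice)
  pl <- probs
  node(v, parents = list(pl), bk = function(n) {
    if (!needs_grad(pl)) return(invisible(NULL))
    G <- array(0, c(HW, K, B))
    for (k in seq_len(K - 1L))
      G[, k + 1L, ] <- -(2 * Y[, k, ] / den[k] - num[k] / den[k]^2) / (K - 1L)
    accum(pl, array(G, d) * n$g)
  })
}

op_neglog_mean <- function(s) {
  sv <- as.numeric(s$v)
  v <- -mean(log(clamp01(sv)))
  sl <- s
  node(v, parents = list(sl), bk = function(n) {
    if (!needs_grad(sl)) return(invisible(NULL))
    g <- numeric(length(sv))
    live <- sv > .eps_prob
    g[live] <- -n$g / (length(sv) * sv[live])
    accum(sl, array(g, dim(sl$v)))
  })
}

op_bce <- function(s, target) {
  sv <- as.numeric(s$v); t <- as.numeric(target)
  v <- -mean(t * log(clamp01(sv)) + (1 - t) * log(clamp01(1 - sv)))
  sl <- s
  node(v, parents = list(sl), bk = function(n) {
    if (!needs_grad(sl)) return(invisible(NULL))
    g <- numeric(length(sv))
    live <- sv > .eps_prob & sv < 1 - .eps_prob
    g[live] <- n$g * (-(t[live] / sv[live]) + (1 - t[live]) / (1 - sv[live])) / length(sv)
    accum(sl, array(g, dim(sl$v)))
  })
}

op_axpy <- function(x, y, a = 1) {
  xl <- x; yl <- y
  node(x$v + a * y$v, parents = list(xl, yl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g)
    if (needs_grad(yl)) accum(yl, a * n$g)
  })
}

op_add_scalar2 <- function(x, y) op_axpy(x, y, 1)

# -- public (array-level) loss API -------------------------------------------

loss_val <- function(x) if (inherits(x, "eg_node")) x else node(x)

#' Supervised segmentation loss
#'
#' Pixel cross-entropy, soft multi-class Dice over the foreground classes,
#' or their sum. Zero iff the probabilities are one-hot correct.
#'
#' @param probs class probabilities, array `(H, W, K, B)` summing to 1 over K
#' @param labels integer labels `(H, W, B)` with values in `[0, K)`
#' @param mode one of `"ce"`, `"dice"`, `"ce+dice"`
#' @param smooth Dice smoothing term
#' @return non-negative scalar
#' @export
supervised_loss <- function(probs, labels, mode = c("ce+dice", "ce", "dice"),
                            smooth = 1e-6) {
  mode <- match.arg(mode)
  nodein <- inherits(probs, "eg_node")
  p <- loss_val(probs)
  out <- switch(mode,
    "ce" = op_ce_loss(p, labels),
    "dice" = op_dice_loss(p, labels, smooth),
    "ce+dice" = op_add_scalar2(op_ce_loss(p, labels),
                               op_dice_loss(p, labels, smooth)))
  if (nodein) out else as.numeric(out$v)
}

#' Generator adversarial loss: -mean log D(G(x))
#' @param scores discriminator scores on generated masks, values in (0, 1]
#' @return scalar, zero iff all scores are 1
#' @export
generator_adversarial_loss <- function(scores) {
  nodein <- inherits(scores, "eg_node")
  out <- op_neglog_mean(loss_val(scores))
  if (nodein) out else as.numeric(out$v)
}

#' Discriminator binary cross-entropy
#' @param scores_real scores on ground-truth (one-hot) masks, target 1
#' @param scores_fake scores on generated probability maps, target 0
#' @return scalar BCE averaged over both batches
#' @export
discriminator_loss <- function(scores_real, scores_fake) {
  nr <- inherits(scores_real, "eg_node")
  r <- loss_val(scores_real); f <- loss_val(scores_fake)
  sr <- as.numeric(r$v); sf <- as.numeric(f$v)
  # single averaged BCE over the concatenated batch
  out_r <- op_bce(r, rep(1, length(sr)))
  out_f <- op_bce(f, rep(0, length(sf)))
  wr <- length(sr) / (length(sr) + length(sf))
  out <- op_axpy2w(out_r, out_f, wr, 1 - wr)
  if (nr) out else as.numeric(out$v)
}

op_axpy2w <- function(x, y, a, b) {
  xl <- x; yl <- y
  node(a * x$v + b * y$v, parents = list(xl, yl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, a * n$g)
    if (needs_grad(yl)) accum(yl, b * n$g)
  })
}

#' Total generator loss: Lsup + lambda * Ladv
#' @param lsup supervised loss (scalar or node)
#' @param ladv adversarial loss (scalar or node)
#' @param lambda non-negative balance weight (default 0.01)
#' @export
total_loss <- function(lsup, ladv, lambda = 0.01) {
  stopifnot(lambda >= 0)
  if (inherits(lsup, "eg_node") || inherits(ladv, "eg_node"))
    op_axpy(loss_val(lsup), loss_val(ladv), lambda)
  else lsup + lambda * ladv
}
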