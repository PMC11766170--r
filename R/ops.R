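# Differentiable ops on (H, W, C, B) arrays. Each op takes nodes (see
# tape.R), returns a node, and registers a backward closure that writes
# into its parents' `g` slots. Heavy kernels live in src/ops.cpp; the
# elementwise and normalisation math is plain vectorised R.

needs_grad <- function(x) {
  !is.null(x$pobj) || !is.null(x$bk) || isTRUE(x$want_grad)
}

dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# ---- convolutions ----------------------------------------------------------

# w: matrix (Cout x K), K = kh*kw*Cin (row order of the im2col buffer);
# b: vector length Cout or NULL.
op_conv2d <- function(x, w, b = NULL, kh, kw, stride = 1L, pad = 0L) {
  d <- dims4(x$v)
  v <- conv2d_fwd_cpp(x$v, w$v, if (is.null(b)) numeric(0) else b$v,
                      kh, kw, stride, pad)
  count_macs(prod(dim(v)) / dim(v)[3] * nrow(w$v) * ncol(w$v))
  xl <- x; wl <- leafify(w); bl <- if (is.null(b)) NULL else leafify(b)
  node(v, parents = list(xl, wl, bl), bk = function(n) {
    res <- conv2d_bwd_cpp(xl$v, wl$v, n$g, kh, kw, stride, pad, needs_grad(xl))
    accum(wl, res$dw)
    if (!is.null(bl)) accum(bl, as.numeric(res$db))
    if (needs_grad(xl)) accum(xl, res$dx)
  })
}

op_dwconv2d <- function(x, w, kh, kw, stride = 1L, pad = 0L) {
  v <- dwconv2d_fwd_cpp(x$v, w$v, kh, kw, stride, pad)
  count_macs(prod(dim(v)) * kh * kw)
  xl <- x; wl <- leafify(w)
  node(v, parents = list(xl, wl), bk = function(n) {
    res <- dwconv2d_bwd_cpp(xl$v, wl$v, n$g, kh, kw, stride, pad, needs_grad(xl))
    accum(wl, res$dw)
    if (needs_grad(xl)) accum(xl, res$dx)
  })
}

# Cross-channel 1-D convolution on (1,1,C,B), zero-padded, odd kernel.
op_conv1d_c <- function(x, w) {
  d <- dims4(x$v); C <- d[3]; B <- d[4]
  k <- length(w$v); half <- (k - 1L) %/% 2L
  X <- matrix(x$v, C, B)
  Xp <- rbind(matrix(0, half, B), X, matrix(0, half, B))
  Y <- matrix(0, C, B)
  for (j in seq_len(k)) Y <- Y + w$v[j] * Xp[j:(j + C - 1L), , drop = FALSE]
  count_macs(k * C * B)
  xl <- x; wl <- leafify(w)
  node(array(Y, d), parents = list(xl, wl), bk = function(n) {
    G <- matrix(n$g, C, B)
    dw <- numeric(k)
    dXp <- matrix(0, C + 2L * half, B)
    for (j in seq_len(k)) {
      rows <- j:(j + C - 1L)
      dw[j] <- sum(Xp[rows, , drop = FALSE] * G)
      dXp[rows, ] <- dXp[rows, ] + wl$v[j] * G
    }
    accum(wl, dw)
    if (needs_grad(xl))
      accum(xl, array(dXp[(half + 1L):(half + C), , drop = FALSE], d))
  })
}

# Dense layer on (1,1,C,B): w (O x C), b length O or NULL.
op_linear <- function(x, w, b = NULL) {
  d <- dims4(x$v); C <- d[3]; B <- d[4]
  X <- matrix(x$v, C, B)
  O <- nrow(w$v)
  Y <- w$v %*% X
  if (!is.null(b)) Y <- Y + b$v
  count_macs(O * C * B)
  xl <- x; wl <- leafify(w); bl <- if (is.null(b)) NULL else leafify(b)
  node(array(Y, c(1L, 1L, O, B)), parents = list(xl, wl, bl), bk = function(n) {
    G <- matrix(n$g, O, B)
    accum(wl, G %*% t(X))
    if (!is.null(bl)) accum(bl, rowSums(G))
    if (needs_grad(xl)) accum(xl, array(crossprod(wl$v, G), d))
  })
}

# Parameters arrive as eg_param objects; wrap them in (possibly frozen)
# leaves. The freeze flag is carried in .eg so module code stays clean.
leafify <- function(p) {
  if (inherits(p, "eg_node")) return(p)
  leaf(p, freeze = isTRUE(.eg$freeze))
}

with_frozen <- function(expr) {
  old <- isTRUE(.eg$freeze)
  .eg$freeze <- TRUE
  on.exit(.eg$freeze <- old)
  expr
}

# ---- normalisation ---------------------------------------------------------

# Batch normalisation over (H, W, B) per channel. `st` is an environment
# holding running statistics (rm, rv); training mode uses batch statistics
# and updates them, eval mode uses the stored ones.
op_bn <- function(x, g, b, st, training, momentum = 0.1, eps = 1e-5) {
  d <- dims4(x$v); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  if (training) {
    mu <- rowMeans(matrix(.colMeans(x$v, HW, C * B), C, B))
    va <- rowMeans(matrix(.colMeans(x$v * x$v, HW, C * B), C, B)) - mu^2
    st$rm <- (1 - momentum) * st$rm + momentum * mu
    st$rv <- (1 - momentum) * st$rv + momentum * va
  } else {
    mu <- st$rm; va <- st$rv
  }
  sd_ <- sqrt(va + eps)
  scale <- g$v / sd_
  Y <- chan_affine_cpp(x$v, scale, b$v - mu * scale)
  xl <- x; gl <- leafify(g); bl <- leafify(b)
  node(Y, parents = list(xl, gl, bl), bk = function(n) {
    res <- bn_bwd_cpp(xl$v, n$g, mu, sd_, scale, training, needs_grad(xl))
    accum(gl, res$s_gx)
    accum(bl, res$s_g)
    if (needs_grad(xl)) accum(xl, res$dx)
  })
}

# Layer normalisation over channels of (1,1,C,B), learnable affine.
op_ln_c <- function(x, g, b, eps = 1e-5) {
  d <- dims4(x$v); C <- d[3]; B <- d[4]
  X <- matrix(x$v, C, B)
  mu <- .colMeans(X, C, B)
  va <- .colMeans(X * X, C, B) - mu^2
  sd_ <- sqrt(va + eps)
  xh <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  Y <- xh * g$v + b$v
  xl <- x; gl <- leafify(g); bl <- leafify(b)
  node(array(Y, d), parents = list(xl, gl, bl), bk = function(n) {
    G <- matrix(n$g, C, B)
    accum(gl, rowSums(G * xh))
    accum(bl, rowSums(G))
    if (needs_grad(xl)) {
      Gh <- G * g$v
      mg <- .colMeans(Gh, C, B)
      mgx <- .colMeans(Gh * xh, C, B)
      DX <- sweep(sweep(sweep(Gh, 2, mg, "-") - sweep(xh, 2, mgx, "*"),
                        2, sd_, "/"), 2, 0, "+")
      accum(xl, array(DX, d))
    }
  })
}

# ---- elementwise -----------------------------------------------------------

op_relu <- function(x) {
  v <- x$v
  v[v < 0] <- 0
  xl <- x
  node(v, parents = list(xl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g * (xl$v > 0))
  })
}

op_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$v))
  xl <- x
  node(v, parents = list(xl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g * v * (1 - v))
  })
}

op_add <- function(x, y) {
  xl <- x; yl <- y
  node(x$v + y$v, parents = list(xl, yl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g)
    if (needs_grad(yl)) accum(yl, n$g)
  })
}

# broadcast helpers ----------------------------------------------------------

bc_cvec <- function(v, HW) {
  # (1,1,C,B) -> full (H*W, C*B) column-constant matrix values
  rep(as.vector(v), each = HW)
}

sum_to_cvec <- function(G, HW, C, B) {
  array(matrix(.colSums(matrix(G, HW, C * B), HW, C * B), C, B),
        c(1L, 1L, C, B))
}

bc_smap <- function(s, C) {
  # (H,W,1,B) -> (H,W,C,B)
  d <- dim(s); HW <- d[1] * d[2]; B <- d[4]
  m <- matrix(s, HW, B)
  array(m[, rep(seq_len(B), each = C), drop = FALSE], c(d[1], d[2], C, B))
}

sum_to_smap <- function(G, H, W, C, B) {
  a <- array(G, c(H * W, C, B))
  array(rowSums(aperm(a, c(1L, 3L, 2L)), dims = 2L), c(H, W, 1L, B))
}

# x + v, v a per-channel vector (1,1,C,B)
op_add_cvec <- function(x, v) {
  d <- dims4(x$v); HW <- d[1] * d[2]
  xl <- x; vl <- v
  node(x$v + array(bc_cvec(v$v, HW), d), parents = list(xl, vl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g)
    if (needs_grad(vl)) accum(vl, sum_to_cvec(n$g, HW, d[3], d[4]))
  })
}

# x + s, s a spatial map (H,W,1,B) broadcast over channels
op_add_smap <- function(x, s) {
  d <- dims4(x$v)
  xl <- x; sl <- s
  node(x$v + bc_smap(s$v, d[3]), parents = list(xl, sl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g)
    if (needs_grad(sl)) accum(sl, sum_to_smap(n$g, d[1], d[2], d[3], d[4]))
  })
}

# x * v, v a per-channel gate (1,1,C,B)
op_mul_cvec <- function(x, v) {
  d <- dims4(x$v); HW <- d[1] * d[2]
  V <- array(bc_cvec(v$v, HW), d)
  xl <- x; vl <- v
  node(x$v * V, parents = list(xl, vl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g * V)
    if (needs_grad(vl)) accum(vl, sum_to_cvec(n$g * xl$v, HW, d[3], d[4]))
  })
}

op_concat_c <- function(x, y) {
  dx <- dims4(x$v); dy_ <- dims4(y$v)
  stopifnot(all(dx[c(1, 2, 4)] == dy_[c(1, 2, 4)]))
  C1 <- dx[3]; C2 <- dy_[3]
  v <- array(0, c(dx[1], dx[2], C1 + C2, dx[4]))
  v[, , seq_len(C1), ] <- x$v
  v[, , C1 + seq_len(C2), ] <- y$v
  xl <- x; yl <- y
  node(v, parents = list(xl, yl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, n$g[, , seq_len(C1), , drop = FALSE])
    if (needs_grad(yl)) accum(yl, n$g[, , C1 + seq_len(C2), , drop = FALSE])
  })
}

# ---- pooling / resampling --------------------------------------------------

op_gap <- function(x) {
  d <- dims4(x$v); HW <- d[1] * d[2]
  v <- sum_to_cvec(x$v, HW, d[3], d[4]) / HW
  xl <- x
  node(v, parents = list(xl), bk = function(n) {
    if (needs_grad(xl))
      accum(xl, array(bc_cvec(n$g / HW, HW), d))
  })
}

op_resize_bilinear <- function(x, Ho, Wo) {
  d <- dims4(x$v)
  xl <- x
  node(resize_bilinear_cpp(x$v, Ho, Wo), parents = list(xl), bk = function(n) {
    if (needs_grad(xl)) accum(xl, resize_bilinear_bwd_cpp(n$g, d[1], d[2]))
  })
}

# ---- softmax ---------------------------------------------------------------

# softmax over the spatial positions, independently per channel and sample
op_softmax_hw <- function(x) {
  d <- dims4(x$v); HW <- d[1] * d[2]
  M <- matrix(x$v, HW, d[3] * d[4])
  M <- exp(sweep(M, 2, apply(M, 2, max), "-"))
  Y <- sweep(M, 2, colSums(M), "/")
  xl <- x
  yv <- array(Y, d)
  node(yv, parents = list(xl), bk = function(n) {
    G <- matrix(n$g, HW, d[3] * d[4])
    s <- colSums(G * Y)
    if (needs_grad(xl)) accum(xl, array(Y * sweep(G, 2, s, "-"), d))
  })
}

# softmax over channels of a (1,1,C,B) vector
op_softmax_c <- function(x) {
  d <- dims4(x$v); C <- d[3]; B <- d[4]
  M <- matrix(x$v, C, B)
  M <- exp(sweep(M, 2, apply(M, 2, max), "-"))
  Y <- sweep(M, 2, colSums(M), "/")
  xl <- x
  node(array(Y, d), parents = list(xl), bk = function(n) {
    G <- matrix(n$g, C, B)
    s <- colSums(G * Y)
    if (needs_grad(xl)) accum(xl, array(Y * sweep(G, 2, s, "-"), d))
  })
}

# per-pixel softmax over channels of (H,W,K,B) (class probabilities)
op_softmax_channels <- function(x) {
  d <- dims4(x$v)
  a <- aperm(x$v, c(3L, 1L, 2L, 4L))
  M <- matrix(a, d[3], d[1] * d[2] * d[4])
  M <- exp(sweep(M, 2, apply(M, 2, max), "-"))
  Y <- sweep(M, 2, colSums(M), "/")
  yv <- aperm(array(Y, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
  xl <- x
  node(yv, parents = list(xl), bk = function(n) {
    G <- matrix(aperm(n$g, c(3L, 1L, 2L, 4L)), d[3], d[1] * d[2] * d[4])
    s <- colSums(G * Y)
    DX <- Y * sweep(G, 2, s, "-")
    if (needs_grad(xl))
      accum(xl, aperm(array(DX, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L)))
  })
}

# ---- attention contractions ------------------------------------------------

# context vector: out[c,b] = sum_p x[p,c,b] * w[p,b];  w is (H,W,1,B)
op_spatial_weighted_sum <- function(x, w) {
  d <- dims4(x$v); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  stopifnot(all(dim(w$v) == c(d[1], d[2], 1L, B)))
  Xa <- array(x$v, c(HW, C, B))
  Wm <- matrix(w$v, HW, B)
  out <- array(0, c(1L, 1L, C, B))
  for (b in seq_len(B)) out[1, 1, , b] <- crossprod(matrix(Xa[, , b], HW, C), Wm[, b])
  xl <- x; wl <- w
  node(out, parents = list(xl, wl), bk = function(n) {
    G <- matrix(n$g, C, B)
    if (needs_grad(xl)) {
      DX <- array(0, c(HW, C, B))
      for (b in seq_len(B)) DX[, , b] <- tcrossprod(Wm[, b], G[, b])
      accum(xl, array(DX, d))
    }
    if (needs_grad(wl)) {
      DW <- matrix(0, HW, B)
      for (b in seq_len(B)) DW[, b] <- matrix(Xa[, , b], HW, C) %*% G[, b]
      accum(wl, array(DW, c(d[1], d[2], 1L, B)))
    }
  })
}

# channel mix: out[p,b] = sum_c a[c,b] * x[p,c,b];  a is (1,1,C,B)
op_channel_weighted_sum <- function(x, a) {
  d <- dims4(x$v); HW <- d[1] * d[2]; C <- d[3]; B <- d[4]
  Xa <- array(x$v, c(HW, C, B))
  Am <- matrix(a$v, C, B)
  out <- matrix(0, HW, B)
  for (b in seq_len(B)) out[, b] <- matrix(Xa[, , b], HW, C) %*% Am[, b]
  xl <- x; al <- a
  node(array(out, c(d[1], d[2], 1L, B)), parents = list(xl, al), bk = function(n) {
    G <- matrix(n$g, HW, B)
    if (needs_grad(xl)) {
      DX <- array(0, c(HW, C, B))
      for (b in seq_len(B)) DX[, , b] <- tcrossprod(G[, b], Am[, b])
      accum(xl, array(DX, d))
    }
    if (needs_grad(al)) {
      DA <- matrix(0, C, B)
      for (b in seq_len(B)) DA[, b] <- crossprod(matrix(Xa[, , b], HW, C), G[, b])
      accum(al, array(DA, c(1L, 1L, C, B)))
    }
  })
}
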