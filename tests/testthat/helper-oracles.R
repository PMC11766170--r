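# Independent reference implementations (naive loops) used as oracles, plus
# fixture builders. These deliberately share no code with the package's
# compute path: convolutions are direct quadruple loops, reductions are
# explicit sums.

eg <- asNamespace("egaunet")

# direct convolution on one sample (H,W,C); wmat (Cout x K), K = C*k*k with
# the package's row order k = (c-1)*kh*kw + (ki-1)*kw + kj
naive_conv <- function(x, wmat, bias = NULL, k = 1L, stride = 1L,
                       pad = (k - 1L) %/% 2L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  Cout <- nrow(wmat)
  out <- array(0, c(Ho, Wo, Cout))
  for (co in seq_len(Cout)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- if (is.null(bias)) 0 else bias[co]
    for (c in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
      hi <- (ho - 1L) * stride - pad + ki
      wi <- (wo - 1L) * stride - pad + kj
      if (hi >= 1L && hi <= H && wi >= 1L && wi <= W)
        acc <- acc + x[hi, wi, c] * wmat[co, (c - 1L) * k * k + (ki - 1L) * k + kj]
    }
    out[ho, wo, co] <- acc
  }
  out
}

naive_dwconv <- function(x, w, stride = 1L) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; k <- dim(w)[1]
  pad <- (k - 1L) %/% 2L
  Ho <- (H + 2 * pad - k) %/% stride + 1L
  Wo <- (W + 2 * pad - k) %/% stride + 1L
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C)) for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      hi <- (ho - 1L) * stride - pad + ki
      wi <- (wo - 1L) * stride - pad + kj
      if (hi >= 1L && hi <= H && wi >= 1L && wi <= W)
        acc <- acc + x[hi, wi, c] * w[ki, kj, c]
    }
    out[ho, wo, c] <- acc
  }
  out
}

# eval-mode batch norm with a layer's parameters and running statistics
naive_bn <- function(x, layer, eps = 1e-5) {
  st <- layer$states$bn
  g <- layer$params$g$v; b <- layer$params$be$v
  out <- x
  for (c in seq_len(dim(x)[3]))
    out[, , c] <- (x[, , c] - st$rm[c]) / sqrt(st$rv[c] + eps) * g[c] + b[c]
  out
}

softmax_vec <- function(v) { e <- exp(v - max(v)); e / sum(e) }

# full GSCA forward on one sample, by loops, from the block's own weights
naive_gsca <- function(block, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  lg <- block$children$logit$params
  logits <- naive_conv(x, lg$w$v, lg$b$v, k = 1L)
  e2 <- array(softmax_vec(as.vector(logits)), c(H, W))
  e3 <- numeric(C)
  for (c in seq_len(C)) for (h in seq_len(H)) for (w in seq_len(W))
    e3[c] <- e3[c] + x[h, w, c] * e2[h, w]
  f1 <- block$children$fc1$params
  mid <- as.vector(f1$w$v %*% e3 + f1$b$v)
  mu <- mean(mid); sd_ <- sqrt(mean((mid - mu)^2) + 1e-5)
  ln <- (mid - mu) / sd_ * block$params$ln_g$v + block$params$ln_b$v
  f2 <- block$children$fc2$params
  e4 <- as.vector(f2$w$v %*% ln + f2$b$v)
  a <- softmax_vec(e4)
  cmap <- matrix(0, H, W)
  for (h in seq_len(H)) for (w in seq_len(W))
    cmap[h, w] <- sum(a * x[h, w, ])
  e6 <- array(softmax_vec(as.vector(cmap)), c(H, W))
  out <- x
  for (c in seq_len(C)) out[, , c] <- x[, , c] + e4[c] + e6
  out
}

# full EMCB forward on one sample (eval mode) from the block's own weights
naive_emcb <- function(block, x) {
  ch <- block$children
  f1 <- naive_bn(naive_conv(x, ch$f1$params$w$v, k = 3L), ch$f1)
  f1 <- pmax(f1, 0)
  dcv <- naive_bn(naive_dwconv(f1, ch$dconv$params$w$v), ch$dconv)
  d <- dim(f1)
  f2 <- array(0, c(d[1], d[2], 2L * d[3]))
  f2[, , seq_len(d[3])] <- f1
  f2[, , d[3] + seq_len(d[3])] <- dcv
  Cg <- 2L * d[3]
  gap <- vapply(seq_len(Cg), function(c) mean(f2[, , c]), 0)
  kw <- block$params$eca$v
  k <- length(kw); half <- (k - 1L) %/% 2L
  gp <- c(rep(0, half), gap, rep(0, half))
  gate <- vapply(seq_len(Cg), function(c) {
    1 / (1 + exp(-sum(kw * gp[c:(c + k - 1L)])))
  }, 0)
  pc <- naive_bn(naive_conv(x, ch$pconv$params$w$v, k = 1L), ch$pconv)
  out <- pc
  for (c in seq_len(Cg)) out[, , c] <- out[, , c] + f2[, , c] * gate[c]
  out
}

# brute-force per-pixel metric recount for K classes
naive_metrics <- function(pred, truth, K) {
  counts <- matrix(0, K, 4, dimnames = list(NULL, c("TP", "FP", "FN", "TN")))
  for (c in 0:(K - 1)) {
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(pred)) {
      p <- pred[i] == c; t <- truth[i] == c
      if (p && t) tp <- tp + 1 else if (p) fp <- fp + 1
      else if (t) fn <- fn + 1 else tn <- tn + 1
    }
    counts[c + 1, ] <- c(tp, fp, fn, tn)
  }
  counts
}

# single-sample wrappers around the package forward
fwd1 <- function(module, x2d) {
  x <- array(x2d, c(dim(x2d)[1], dim(x2d)[2], dim(x2d)[3], 1L))
  y <- forward(module, x)
  array(y, dim(y)[1:3])
}

set_all_params <- function(module, value = 0) {
  for (p in eg$all_params(module)) p$v <- 0 * p$v + value
  invisible(module)
}

# a small stage plan for fast unit tests (same 5-stage layout, thin widths)
small_plan <- function() default_stage_plan(expansion = c(2, 2, 2, 2, 2))

# ---- DICOM fixture writer (independent byte-level construction) -----------

write_test_dicom <- function(path, pixels, slope = 1, intercept = 0,
                             explicit = TRUE, bits = 16L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  pad_even <- function(s) if (nchar(s) %% 2L == 1L) paste0(s, " ") else s
  elem_str <- function(group, el, vr, value, force_explicit = FALSE) {
    value <- pad_even(value)
    u16(group); u16(el)
    if (explicit || force_explicit) {
      writeChar(vr, con, eos = NULL); u16(nchar(value))
    } else u32(nchar(value))
    writeChar(value, con, eos = NULL)
  }
  elem_us <- function(group, el, value) {
    u16(group); u16(el)
    if (explicit) { writeChar("US", con, eos = NULL); u16(2L) } else u32(2L)
    u16(value)
  }
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  elem_str(0x0002, 0x0010, "UI", ts, force_explicit = TRUE)
  rows <- nrow(pixels); cols <- ncol(pixels)
  elem_us(0x0028, 0x0010, rows)
  elem_us(0x0028, 0x0011, cols)
  elem_us(0x0028, 0x0100, bits)
  elem_us(0x0028, 0x0103, 0L)
  elem_str(0x0028, 0x1052, "DS", as.character(intercept))
  elem_str(0x0028, 0x1053, "DS", as.character(slope))
  vals <- as.integer(t(pixels))  # row-major
  nbytes <- length(vals) * (bits %/% 8L)
  u16(0x7fe0); u16(0x0010)
  if (explicit) { writeChar("OW", con, eos = NULL); u16(0L); u32(nbytes) }
  else u32(nbytes)
  writeBin(vals, con, size = bits %/% 8L, endian = "little")
  invisible(path)
}
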