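# Global Spatial-Channel Attention block.

test_that("spatial context weights are a softmax over positions", {
  set.seed(10)
  blk <- gsca_block(3L)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  w <- spatial_context_weights(blk, x)
  expect_equal(dim(w), c(4L, 4L, 1L, 2L))
  expect_true(all(w >= 0))
  expect_equal(apply(w, 4, sum), c(1, 1), tolerance = 1e-6)
  # zero conv weights -> uniform 1/(HW)
  set_all_params(blk)
  w0 <- spatial_context_weights(blk, x)
  expect_equal(as.vector(w0), rep(1 / 16, 32), tolerance = 1e-12)
})

test_that("hand-computed softmax example: logits (0, ln 2, 0, 0)", {
  # softmax = (1, 2, 1, 1)/5
  blk <- gsca_block(1L)
  set_all_params(blk)
  blk$children$logit$params$w$v[] <- 1
  x <- array(c(0, log(2), 0, 0), c(2, 2, 1, 1))
  w <- spatial_context_weights(blk, x)
  expect_equal(as.vector(w), c(1, 2, 1, 1) / 5, tolerance = 1e-10)
})

test_that("global context is the weighted spatial sum", {
  set.seed(11)
  x <- array(rnorm(2 * 2 * 3), c(2, 2, 3, 1))
  # uniform weights -> per-channel mean
  wu <- array(1 / 4, c(2, 2, 1, 1))
  e3 <- global_context(x, wu)
  expect_equal(as.vector(e3), apply(x[, , , 1], 3, mean), tolerance = 1e-12)
  # constant channel -> that constant for any weights
  x[, , 2, 1] <- 0.7
  wr <- array(softmax_vec(rnorm(4)), c(2, 2, 1, 1))
  expect_equal(global_context(x, wr)[1, 1, 2, 1], 0.7, tolerance = 1e-12)
  # brute-force double loop
  ref <- numeric(3)
  for (c in 1:3) for (h in 1:2) for (w in 1:2)
    ref[c] <- ref[c] + x[h, w, c, 1] * wr[h, w, 1, 1]
  expect_equal(as.vector(global_context(x, wr)), ref, tolerance = 1e-12)
  expect_error(global_context(x, array(1, c(3, 3, 1, 1))), "shape")
})

test_that("channel excitation preserves shape; zero weights give zero", {
  set.seed(12)
  blk <- gsca_block(6L)
  e3 <- array(rnorm(6 * 2), c(1, 1, 6, 2))
  e4 <- channel_excitation(blk, e3)
  expect_equal(dim(e4), dim(e3))
  set_all_params(blk)
  expect_equal(max(abs(channel_excitation(blk, e3))), 0)
})

test_that("layer normalisation with identity kernels reproduces (1, -1)", {
  blk <- gsca_block(2L, hidden = 2L)
  set_all_params(blk)
  blk$children$fc1$params$w$v <- diag(2)
  blk$children$fc2$params$w$v <- diag(2)
  blk$params$ln_g$v[] <- 1
  e3 <- array(c(1, -1), c(1, 1, 2, 1))
  # LN of (1,-1): mean 0, population sd 1 -> unchanged (up to eps)
  expect_equal(as.vector(channel_excitation(blk, e3)), c(1, -1), tolerance = 1e-4)
})

test_that("spatial reweighting is a unit-sum map; E4 constant gives channel mean", {
  set.seed(13)
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  e4 <- array(rnorm(4 * 2), c(1, 1, 4, 2))
  e6 <- spatial_reweight(x, e4)
  expect_equal(apply(e6, 4, sum), c(1, 1), tolerance = 1e-6)
  expect_error(spatial_reweight(x, array(0, c(1, 1, 3, 2))), "channel")
  # singleton spatial input: softmax of one entry is 1
  x1 <- array(rnorm(2), c(1, 1, 2, 1))
  expect_equal(as.vector(spatial_reweight(x1, array(rnorm(2), c(1, 1, 2, 1)))), 1)
})

test_that("gsca_forward matches the naive loop oracle and the zero-weight form", {
  set.seed(14)
  for (rep in 1:3) {
    blk <- gsca_block(5L)
    x <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
    expect_equal(fwd1(blk, x), naive_gsca(blk, x), tolerance = 1e-10)
  }
  blk <- gsca_block(3L)
  set_all_params(blk)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  # all weights zero: E4 = 0 and the channel softmax is uniform, so the
  # spatial map is the softmax of the per-pixel channel mean
  e6 <- array(softmax_vec(as.vector(apply(x, c(1, 2), mean))), c(4, 4))
  expected <- x
  for (c in 1:3) expected[, , c] <- x[, , c] + e6
  expect_equal(fwd1(blk, x), expected, tolerance = 1e-12)
  # for a constant input the spatial map degenerates to uniform 1/(HW)
  xc <- array(0.3, c(4, 4, 3))
  expect_equal(fwd1(blk, xc), xc + 1 / 16, tolerance = 1e-12)
})

test_that("gsca is batch-permutation equivariant and lets gradients reach the input", {
  set.seed(15)
  blk <- gsca_block(4L)
  x <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  y <- forward(blk, x)
  perm <- c(3L, 1L, 2L)
  yp <- forward(blk, x[, , , perm, drop = FALSE])
  expect_equal(yp, y[, , , perm, drop = FALSE], tolerance = 1e-12)
  # additive residual guarantees a gradient path to the input
  eg$tape_start()
  xn <- eg$node(x); xn$want_grad <- TRUE
  out <- blk$forward(xn, training = FALSE)
  loss <- eg$node(sum(out$v^2) / 2, parents = list(out),
                  bk = function(n) eg$accum(out, out$v * n$g))
  eg$tape_backward(loss)
  g <- xn$g
  eg$tape_stop()
  expect_true(all(is.finite(g)))
  expect_gt(max(abs(g)), 0)
})
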