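# Numerical gradient checks of the autodiff ops against central
# finite differences, plus the tape's freezing contract.

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# analytic input-gradient of sum(op(x)^2)/2 vs finite differences
grad_check <- function(build, x0, tol = 1e-5) {
  sq <- function(y) eg$node(sum(y$v^2) / 2, parents = list(y),
                            bk = function(n) eg$accum(y, y$v * n$g))
  eg$tape_start()
  xn <- eg$node(x0); xn$want_grad <- TRUE
  eg$tape_backward(sq(build(xn)))
  ga <- xn$g
  eg$tape_stop()
  gn <- num_grad(function(x) sum(build(eg$node(x))$v^2) / 2, x0)
  expect_lt(max(abs(ga - gn)) / max(1e-8, max(abs(gn))), tol)
}

test_that("convolution ops match finite-difference gradients", {
  set.seed(101)
  x0 <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  w <- eg$new_param(matrix(rnorm(4 * 27, sd = 0.3), 4, 27))
  b <- eg$new_param(rnorm(4))
  wd <- eg$new_param(array(rnorm(27, sd = 0.3), c(3, 3, 3)))
  wk <- eg$new_param(rnorm(5))
  grad_check(function(x) eg$op_conv2d(x, w, b, 3, 3, 1, 1), x0)
  grad_check(function(x) eg$op_conv2d(x, w, b, 3, 3, 2, 1), x0)
  grad_check(function(x) eg$op_dwconv2d(x, wd, 3, 3, 1, 1), x0)
  grad_check(function(x) eg$op_dwconv2d(x, wd, 3, 3, 2, 1), x0)
  grad_check(function(x) eg$op_conv1d_c(x, wk),
             array(rnorm(7 * 2), c(1, 1, 7, 2)))
})

test_that("normalisation, softmax and resampling ops match finite differences", {
  set.seed(102)
  x0 <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  v0 <- array(rnorm(3 * 2), c(1, 1, 3, 2))
  gg <- eg$new_param(runif(3, 0.5, 1.5)); bb <- eg$new_param(rnorm(3))
  st <- new.env(); st$rm <- rnorm(3) * 0.1; st$rv <- rep(1.3, 3)
  # training-mode BN differentiates through the batch statistics; central
  # differences carry a larger truncation error there
  grad_check(function(x) {
    st2 <- new.env(); st2$rm <- numeric(3); st2$rv <- rep(1, 3)
    eg$op_bn(x, gg, bb, st2, TRUE)
  }, x0, tol = 1e-3)
  grad_check(function(x) eg$op_bn(x, gg, bb, st, FALSE), x0)
  grad_check(function(x) eg$op_ln_c(x, gg, bb), v0, tol = 1e-4)
  grad_check(function(x) eg$op_softmax_hw(x), x0)
  grad_check(function(x) eg$op_softmax_channels(x), x0)
  grad_check(function(x) eg$op_softmax_c(x), v0)
  grad_check(function(x) eg$op_resize_bilinear(x, 10, 12), x0)
  grad_check(function(x) eg$op_resize_bilinear(x, 3, 4), x0)
  grad_check(function(x) eg$op_gap(x), x0)
})

test_that("attention contractions and broadcasts match finite differences", {
  set.seed(103)
  x0 <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  v0 <- array(rnorm(3 * 2), c(1, 1, 3, 2))
  s0 <- array(rnorm(4 * 5 * 2), c(4, 5, 1, 2))
  grad_check(function(x) eg$op_spatial_weighted_sum(x, eg$node(s0)), x0)
  grad_check(function(w) eg$op_spatial_weighted_sum(eg$node(x0), w), s0)
  grad_check(function(x) eg$op_channel_weighted_sum(x, eg$node(v0)), x0)
  grad_check(function(a) eg$op_channel_weighted_sum(eg$node(x0), a), v0)
  grad_check(function(x) eg$op_add_cvec(x, eg$node(v0)), x0)
  grad_check(function(v) eg$op_add_cvec(eg$node(x0), v), v0)
  grad_check(function(x) eg$op_add_smap(x, eg$node(s0)), x0)
  grad_check(function(s) eg$op_add_smap(eg$node(x0), s), s0)
  grad_check(function(x) eg$op_mul_cvec(x, eg$node(v0)), x0)
  grad_check(function(v) eg$op_mul_cvec(eg$node(x0), v), v0)
  grad_check(function(x) eg$op_concat_c(x, eg$node(x0)), x0)
})

test_that("frozen leaves receive no gradient, unfrozen ones do", {
  set.seed(104)
  w <- eg$new_param(matrix(rnorm(8), 2, 4))
  x <- array(rnorm(3 * 3 * 4 * 1), c(3, 3, 4, 1))
  run <- function(freeze) {
    eg$zero_grads(list(w))
    eg$tape_start()
    y <- if (freeze) eg$with_frozen(eg$op_conv2d(eg$node(x), w, NULL, 1, 1, 1, 0))
    else eg$op_conv2d(eg$node(x), w, NULL, 1, 1, 1, 0)
    loss <- eg$node(sum(y$v^2) / 2, parents = list(y),
                    bk = function(n) eg$accum(y, y$v * n$g))
    eg$tape_backward(loss)
    eg$tape_stop()
    max(abs(w$g))
  }
  expect_gt(run(FALSE), 0)
  expect_identical(run(TRUE), 0)
})
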