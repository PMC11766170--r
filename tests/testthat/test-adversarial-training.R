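# Losses (closed forms) and the adversarial training loop contracts.

test_that("supervised loss closed forms", {
  # one-hot correct probabilities: zero loss in every mode
  lab <- array(c(0L, 1L, 1L, 0L), c(2, 2, 1))
  probs <- one_hot_mask(lab, 2L)
  for (m in c("ce", "dice", "ce+dice"))
    expect_equal(supervised_loss(probs, lab, m), 0, tolerance = 1e-5)
  # single pixel, 2 classes, probability 1/2 on the truth: CE = ln 2
  p <- array(c(0.5, 0.5), c(1, 1, 2, 1))
  l <- array(1L, c(1, 1, 1))
  expect_equal(supervised_loss(p, l, "ce"), log(2), tolerance = 1e-9)
  # disjoint masks: Dice loss -> 1 as the smoothing vanishes
  lab2 <- array(1L, c(2, 2, 1))
  pred0 <- one_hot_mask(array(0L, c(2, 2, 1)), 2L)
  expect_equal(supervised_loss(pred0, lab2, "dice", smooth = 1e-12), 1,
               tolerance = 1e-6)
  expect_error(supervised_loss(p, array(5L, c(1, 1, 1)), "ce"), "\\[0, K\\)")
})

test_that("adversarial loss closed forms and clamping", {
  expect_equal(generator_adversarial_loss(1.0), 0)
  expect_equal(generator_adversarial_loss(0.5), log(2), tolerance = 1e-12)
  expect_equal(generator_adversarial_loss(c(1.0, 0.5)), log(2) / 2,
               tolerance = 1e-12)
  expect_true(is.finite(generator_adversarial_loss(0)))   # clamped, not -Inf
  expect_equal(discriminator_loss(1, 0), 0)
  expect_equal(discriminator_loss(0.5, 0.5), log(2), tolerance = 1e-12)
  # label-swap symmetry: scoring (real, fake) equals scoring (1-fake, 1-real)
  a <- c(0.3, 0.8); b <- c(0.6, 0.1)
  expect_equal(discriminator_loss(a, b), discriminator_loss(1 - b, 1 - a),
               tolerance = 1e-12)
  expect_true(is.finite(discriminator_loss(0, 1)))
})

test_that("total loss is Lsup + lambda * Ladv", {
  expect_equal(total_loss(0.5, 0.7, 0.01), 0.507)
  expect_equal(total_loss(0.42, 99, 0), 0.42)
  expect_equal(total_loss(0.9, 0, 1), 0.9)
  expect_error(total_loss(1, 1, -0.1), "lambda")
})

test_that("discriminator scores lie in (0,1) per batch item", {
  d <- build_discriminator(3L, seed = 40)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  s <- discriminate(d, x)
  expect_length(s, 4L)
  expect_true(all(s > 0 & s < 1))
  expect_error(discriminate(d, array(0, c(32, 32, 2, 1))), "mask")
})

make_tiny_data <- function(n = 6, size = 32, seed = 5) {
  generate_phantoms(phantom_config(n_samples = n, image_size = size,
                                   seed = seed))
}

test_that("discriminator parameters are untouched by generator steps and
           updated exactly at the configured period", {
  data <- make_tiny_data()
  gen <- build_egaunet(5L, small_plan(), seed = 41)
  disc <- build_discriminator(5L, seed = 42)
  dp_before <- lapply(eg$all_params(disc), function(p) p$v)
  cfg <- train_config(epochs = 2, batch_size = 2, disc_update_period = 3,
                      seed = 41, augment = FALSE, max_iters = 2,
                      lr_milestones = integer(0))
  res <- train(gen, disc, data, cfg)   # 2 iterations < period: no update
  dp_after <- lapply(eg$all_params(disc), function(p) p$v)
  expect_identical(dp_before, dp_after)
  expect_true(all(is.na(res$history$d_loss)))
  # now run past the period: updates exactly at iterations 3, 6
  cfg2 <- train_config(epochs = 3, batch_size = 2, disc_update_period = 3,
                       seed = 41, augment = FALSE, max_iters = 7,
                       lr_milestones = integer(0))
  res2 <- train(gen, disc, data, cfg2)
  upd <- res2$history$iteration[!is.na(res2$history$d_loss)]
  expect_identical(upd, c(3, 6))
  dp_final <- lapply(eg$all_params(disc), function(p) p$v)
  expect_false(identical(dp_after, dp_final))
})

test_that("lambda = 0 with discriminator updates disabled reproduces plain
           supervised training exactly", {
  data <- make_tiny_data()
  g1 <- build_egaunet(5L, small_plan(), seed = 43)
  g2 <- build_egaunet(5L, small_plan(), seed = 43)
  disc <- build_discriminator(5L, seed = 44)
  cfg_sup <- train_config(epochs = 1, batch_size = 2, adversarial = FALSE,
                          seed = 50, augment = FALSE, lr_milestones = integer(0))
  cfg_l0 <- train_config(epochs = 1, batch_size = 2, lambda_adv = 0,
                         disc_updates = FALSE, seed = 50, augment = FALSE,
                         lr_milestones = integer(0))
  r1 <- train(g1, NULL, data, cfg_sup)
  r2 <- train(g2, disc, data, cfg_l0)
  v1 <- lapply(eg$all_params(g1), function(p) p$v)
  v2 <- lapply(eg$all_params(g2), function(p) p$v)
  expect_identical(v1, v2)
  expect_equal(r1$history$ltotal, r2$history$ltotal)
})

test_that("training histories are finite; empty data is rejected", {
  data <- make_tiny_data(4)
  gen <- build_egaunet(5L, small_plan(), seed = 45)
  disc <- build_discriminator(5L, seed = 46)
  cfg <- train_config(epochs = 1, batch_size = 2, disc_update_period = 2,
                      seed = 45, augment = TRUE, lr_milestones = integer(0))
  res <- train(gen, disc, data, cfg, val_data = data[1:2])
  h <- res$history
  expect_true(all(is.finite(h$lsup)))
  expect_true(all(is.finite(h$ltotal)))
  expect_true(all(is.finite(h$d_loss[!is.na(h$d_loss)])))
  expect_equal(nrow(res$val_metrics), 1L)
  expect_true(all(c("epoch", "Dice", "Jaccard") %in% colnames(res$val_metrics)))
  expect_error(train(gen, disc, list(), cfg), "empty")
})

test_that("a briefly trained discriminator separates truth from noise maps", {
  set.seed(47)
  data <- make_tiny_data(4, seed = 47)
  disc <- build_discriminator(5L, seed = 47)
  dp <- eg$all_params(disc)
  opt <- adam(dp, lr = 1e-3)
  real <- one_hot_mask(array(vapply(data, function(s) s$mask, data[[1]]$mask),
                             c(32, 32, 4)), 5L)
  fake <- array(runif(32 * 32 * 5 * 4), c(32, 32, 5, 4))
  # normalise fake to a per-pixel probability map
  for (b in 1:4) for (h in 1:32) for (w in 1:32)
    fake[h, w, , b] <- fake[h, w, , b] / sum(fake[h, w, , b])
  for (step in 1:15) {
    eg$zero_grads(dp)
    eg$tape_start()
    sr <- disc$forward(eg$node(real), training = TRUE)
    sf <- disc$forward(eg$node(fake), training = TRUE)
    dl <- discriminator_loss(sr, sf)
    eg$tape_backward(dl)
    eg$tape_stop()
    adam_step(opt)
  }
  expect_gt(mean(discriminate(disc, real, training = TRUE)),
            mean(discriminate(disc, fake, training = TRUE)))
})
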