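# Generative-adversarial training loop. Every iteration updates the
# generator with L_total = L_sup + lambda * L_adv while the discriminator is
# frozen; every `disc_update_period`-th iteration additionally takes one
# discriminator step on (one-hot truth, detached generator output). Both
# parties use Adam at the configured learning rate with multi-step decay.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, initial learning rate
#' 0.001, batch size 8, 100 epochs, lambda = 0.01, discriminator update
#' every 30 iterations, multi-step learning-rate decay.
#'
#' @param learning_rate initial Adam learning rate
#' @param epochs training epochs
#' @param batch_size images per generator step
#' @param lambda_adv weight of the adversarial term (>= 0)
#' @param disc_update_period generator iterations between discriminator
#'   updates (>= 1)
#' @param lr_milestones epochs at which the learning rate is multiplied by
#'   `lr_gamma`
#' @param lr_gamma decay factor
#' @param seed drives weight init (if models are built inside [train()]),
#'   shuffling and augmentation
#' @param loss_mode supervised loss: `"ce"`, `"dice"` or `"ce+dice"`
#' @param adversarial enable the adversarial term and discriminator updates
#' @param disc_updates allow discriminator updates (disable to freeze a
#'   discriminator while keeping the adversarial loss term)
#' @param augment random horizontal flip and +/-10 degree rotation
#' @param max_iters stop after this many generator iterations (NULL: run
#'   all epochs)
#' @return a validated `train_config` list
#' @export
train_config <- function(learning_rate = 0.001, epochs = 100L, batch_size = 8L,
                         lambda_adv = 0.01, disc_update_period = 30L,
                         lr_milestones = c(50L, 80L), lr_gamma = 0.1,
                         seed = 1L, loss_mode = "ce+dice", adversarial = TRUE,
                         disc_updates = TRUE, augment = TRUE, max_iters = NULL) {
  cfg <- list(learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), lambda_adv = lambda_adv,
              disc_update_period = as.integer(disc_update_period),
              lr_milestones = as.integer(lr_milestones), lr_gamma = lr_gamma,
              seed = as.integer(seed), loss_mode = loss_mode,
              adversarial = adversarial, disc_updates = disc_updates,
              augment = augment, max_iters = max_iters)
  problems <- character()
  if (cfg$lambda_adv < 0) problems <- c(problems, "lambda_adv must be >= 0")
  if (cfg$disc_update_period < 1L) problems <- c(problems, "disc_update_period must be >= 1")
  if (cfg$batch_size < 1L) problems <- c(problems, "batch_size must be >= 1")
  if (cfg$learning_rate <= 0) problems <- c(problems, "learning_rate must be positive")
  if (!cfg$loss_mode %in% c("ce", "dice", "ce+dice"))
    problems <- c(problems, "loss_mode must be ce, dice or ce+dice")
  if (length(problems)) stop(paste(problems, collapse = "; "))
  class(cfg) <- "train_config"
  cfg
}

# random horizontal flip + small rotation; masks use nearest neighbour
augment_pair <- function(image, mask, max_deg = 10) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (stats::runif(1) < 0.5) {
    image <- image[, W:1, , drop = FALSE]
    mask <- mask[, W:1, drop = FALSE]
  }
  ang <- stats::runif(1, -max_deg, max_deg) * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- cy + cos(ang) * gy - sin(ang) * gx
  sx <- cx + sin(ang) * gy + cos(ang) * gx
  syc <- pmin(pmax(sy, 1), H); sxc <- pmin(pmax(sx, 1), W)
  y0 <- floor(syc); x0 <- floor(sxc)
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  ty <- syc - y0; tx <- sxc - x0
  im <- image[, , 1]
  at <- function(yy, xx) im[cbind(as.vector(yy), as.vector(xx))]
  v <- (1 - ty) * (1 - tx) * at(y0, x0) + ty * (1 - tx) * at(y1, x0) +
    (1 - ty) * tx * at(y0, x1) + ty * tx * at(y1, x1)
  yn <- pmin(pmax(round(syc), 1), H); xn <- pmin(pmax(round(sxc), 1), W)
  list(image = array(v, c(H, W, 1L)),
       mask = matrix(mask[cbind(as.vector(yn), as.vector(xn))], H, W))
}

stack_batch <- function(pairs, idx, augment) {
  H <- dim(pairs[[idx[1]]]$image)[1]; W <- dim(pairs[[idx[1]]]$image)[2]
  nb <- length(idx)
  x <- array(0, c(H, W, 1L, nb))
  y <- array(0L, c(H, W, nb))
  for (j in seq_len(nb)) {
    p <- pairs[[idx[j]]]
    if (augment) p <- augment_pair(p$image, p$mask)
    x[, , 1L, j] <- p$image
    y[, , j] <- p$mask
  }
  list(x = x, y = y)
}

#' Train a segmentation generator (optionally adversarially)
#'
#' @param generator an `egaunet_model` from [build_egaunet()]
#' @param discriminator a [build_discriminator()] module, or NULL for plain
#'   supervised training
#' @param data list of samples, each `list(image = (H,W,1), mask = (H,W))`
#' @param config a [train_config()]
#' @param checkpoint_path if set, the generator checkpoint is (re)written at
#'   the end of every epoch
#' @param val_data optional held-out samples; evaluated at the end of every
#'   epoch and returned as a per-epoch metric table
#' @param verbose print per-epoch progress
#' @return `list(generator, history, val_metrics)`; history is a data.frame
#'   with one row per generator iteration (lsup, ladv, ltotal, d_loss),
#'   val_metrics one row per epoch (NULL without `val_data`)
#' @export
train <- function(generator, discriminator = NULL, data, config = train_config(),
                  checkpoint_path = NULL, val_data = NULL, verbose = FALSE) {
  if (!length(data)) stop("empty training data")
  stopifnot(inherits(config, "train_config"))
  use_adv <- config$adversarial && !is.null(discriminator) && config$lambda_adv > 0
  do_dupd <- config$adversarial && !is.null(discriminator) && config$disc_updates
  K <- generator$num_classes
  gp <- all_params(generator)
  opt_g <- adam(gp, lr = config$learning_rate)
  dp <- NULL; opt_d <- NULL
  if (do_dupd || use_adv) dp <- all_params(discriminator)
  if (do_dupd) opt_d <- adam(dp, lr = config$learning_rate)
  set.seed(config$seed)
  it <- 0L
  hist <- list()
  val_rows <- list()
  n <- length(data)
  for (epoch in seq_len(config$epochs)) {
    lr_now <- config$learning_rate *
      config$lr_gamma^sum(epoch > config$lr_milestones)
    opt_g$lr <- lr_now
    if (do_dupd) opt_d$lr <- lr_now
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
      bat <- stack_batch(data, idx, config$augment)
      it <- it + 1L
      # --- generator step (discriminator frozen) ---
      zero_grads(gp)
      tape_start()
      logits <- generator$forward(node(bat$x), training = TRUE)
      probs <- op_softmax_channels(logits)
      lsup <- supervised_loss(probs, bat$y, config$loss_mode)
      if (use_adv) {
        scores <- with_frozen(discriminator$forward(probs, training = FALSE))
        ladv <- generator_adversarial_loss(scores)
        ltot <- total_loss(lsup, ladv, config$lambda_adv)
      } else {
        ladv <- node(0)
        ltot <- lsup
      }
      if (!is.finite(ltot$v))
        stop("non-finite loss at iteration ", it, " (lsup=", lsup$v,
             ", ladv=", ladv$v, ")")
      tape_backward(ltot)
      fake <- probs$v   # detached copy for the discriminator step
      tape_stop()
      adam_step(opt_g)
      # --- scheduled discriminator step ---
      dls <- NA_real_
      if (do_dupd && it %% config$disc_update_period == 0L) {
        zero_grads(dp)
        tape_start()
        sr <- discriminator$forward(node(one_hot_mask(bat$y, K)), training = TRUE)
        sf <- discriminator$forward(node(fake), training = TRUE)
        dl <- discriminator_loss(sr, sf)
        tape_backward(dl)
        tape_stop()
        adam_step(opt_d)
        dls <- as.numeric(dl$v)
      }
      hist[[it]] <- c(iteration = it, epoch = epoch,
                      lsup = as.numeric(lsup$v), ladv = as.numeric(ladv$v),
                      ltotal = as.numeric(ltot$v), d_loss = dls)
      if (!is.null(config$max_iters) && it >= config$max_iters) break
    }
    if (!is.null(checkpoint_path)) save_checkpoint(generator, checkpoint_path)
    if (!is.null(val_data)) {
      rs <- get(".Random.seed", globalenv())  # evaluation must not move RNG
      vr <- evaluate_model(generator, val_data)$aggregate
      assign(".Random.seed", rs, globalenv())
      val_rows[[epoch]] <- c(epoch = epoch, vr)
    }
    if (verbose) {
      h <- hist[[it]]
      message(sprintf("epoch %d it %d lsup %.4f ltotal %.4f", epoch, it,
                      h[["lsup"]], h[["ltotal"]]))
    }
    if (!is.null(config$max_iters) && it >= config$max_iters) break
  }
  history <- as.data.frame(do.call(rbind, hist))
  val_metrics <- if (length(val_rows)) as.data.frame(do.call(rbind, val_rows))
  list(generator = generator, history = history, val_metrics = val_metrics)
}

#' Write a training history as CSV
#' @param history data.frame from [train()]
#' @param path output file
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
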