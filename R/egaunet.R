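# Model assembly: encoder -> GSCA on the skip features and the deepest
# feature -> decoder -> K-class head, plus inference and profiling.

#' Build the EGAUNet segmentation network
#'
#' @param num_classes number of label classes K (background included)
#' @param plan encoder [default_stage_plan()]
#' @param in_channels input image channels (grayscale: 1)
#' @param use_gsca attach Global Spatial-Channel Attention blocks
#' @param use_emcb use EMCBs in the decoder (FALSE: plain double convs)
#' @param gsca_skips_only apply GSCA to the four skip features only,
#'   leaving the deepest feature untouched
#' @param seed if given, the RNG is seeded locally so two builds with the
#'   same seed have identical initial weights
#' @return an `egaunet_model`
#' @export
build_egaunet <- function(num_classes = 5L, plan = default_stage_plan(),
                          in_channels = 1L, use_gsca = TRUE, use_emcb = TRUE,
                          gsca_skips_only = FALSE, seed = NULL) {
  if (num_classes < 1L) stop("num_classes must be >= 1")
  validate_stage_plan(plan)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  ch <- list(encoder = encoder_build(plan, in_channels))
  if (use_gsca) {
    natt <- if (gsca_skips_only) 4L else 5L
    for (s in seq_len(natt))
      ch[[sprintf("gsca%d", s)]] <- gsca_block(plan$stage_channels[s])
  }
  ch$decoder <- decoder_build(num_classes, plan$stage_channels, use_emcb)
  fwd <- function(x, training = FALSE) {
    feats <- ch$encoder$forward(x, training)
    if (use_gsca) {
      for (s in 1:4) feats[[s]] <- ch[[sprintf("gsca%d", s)]]$forward(feats[[s]], training)
      if (!gsca_skips_only)
        feats[[5]] <- ch$gsca5$forward(feats[[5]], training)
    }
    ch$decoder$forward(feats, training)
  }
  m <- mk_module(fwd, children = ch)
  m$num_classes <- as.integer(num_classes)
  m$in_channels <- as.integer(in_channels)
  m$plan <- plan
  m$flags <- list(use_gsca = use_gsca, use_emcb = use_emcb,
                  gsca_skips_only = gsca_skips_only)
  class(m) <- c("egaunet_model", class(m))
  m
}

check_image <- function(model, image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 4L)
    stop("image must be an (H, W, C, B) array")
  if (d[3] != model$in_channels)
    stop("expected ", model$in_channels, " input channel(s), got ", d[3])
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial size must be divisible by 32")
  invisible(d)
}

#' Per-pixel class probabilities
#'
#' Runs the network in eval mode (batch norm uses running statistics, so
#' repeated calls are bit-identical) and applies a per-pixel softmax.
#'
#' @param model from [build_egaunet()]
#' @param image array `(H, W, C, B)`, values in `[0, 1]`
#' @return probability array `(H, W, K, B)` summing to 1 over K
#' @export
predict_probs <- function(model, image) {
  check_image(model, image)
  op_softmax_channels(model$forward(node(image), training = FALSE))$v
}

#' Predicted label mask (argmax over classes)
#' @inheritParams predict_probs
#' @return integer array `(H, W, B)` with values in `[0, K)`
#' @export
predict_labels <- function(model, image) {
  p <- predict_probs(model, image)
  d <- dim(p)
  m <- matrix(aperm(p, c(3L, 1L, 2L, 4L)), d[3], d[1] * d[2] * d[4])
  array(max.col(t(m), ties.method = "first") - 1L, c(d[1], d[2], d[4]))
}

#' Parameter count, serialized size and FLOPs of a model
#'
#' Conventions (frozen): size assumes 4 bytes per parameter and 2^20 bytes
#' per MB; GFLOPs counts 2 floating-point operations per multiply-accumulate
#' of the convolutional/linear layers (normalisation, softmax and
#' resampling are not counted), measured by an instrumented forward pass at
#' batch size 1.
#'
#' @param model a model (generator or discriminator)
#' @param input_size `c(C, H, W)` of the profiled input
#' @return a `model_profile` list: `parameter_count`, `size_mb`, `gflops`,
#'   `gmacs`, `input_size`
#' @export
profile_model <- function(model, input_size = c(1L, 256L, 256L)) {
  np <- n_params(model)
  prof <- new.env(parent = emptyenv())
  prof$macs <- 0
  .eg$profile <- prof
  on.exit(.eg$profile <- NULL)
  x <- array(0, c(input_size[2], input_size[3], input_size[1], 1L))
  invisible(model$forward(node(x), training = FALSE))
  structure(list(parameter_count = np,
                 size_mb = np * 4 / 2^20,
                 gmacs = prof$macs / 1e9,
                 gflops = 2 * prof$macs / 1e9,
                 input_size = input_size),
            class = "model_profile")
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("parameters : %d\n", x$parameter_count))
  cat(sprintf("size       : %.3f MB (4 bytes/parameter, 2^20 bytes/MB)\n", x$size_mb))
  cat(sprintf("GFLOPs     : %.2f at %s (2 FLOPs per MAC, conv/linear only)\n",
              x$gflops, paste(x$input_size, collapse = "x")))
  invisible(x)
}

# ---- checkpointing ---------------------------------------------------------

#' Save model weights and running statistics
#'
#' A single file holding every learnable array keyed by hierarchical module
#' path, batch-norm running statistics, and a manifest (class count, plan,
#' flags, format version).
#'
#' @param model an `egaunet_model` (or any module with a manifest)
#' @param path output file
#' @export
save_checkpoint <- function(model, path) {
  ps <- all_params(model)
  ss <- all_states(model)
  obj <- list(format = "egaunet-checkpoint-1",
              manifest = list(num_classes = model$num_classes,
                              in_channels = model$in_channels,
                              plan = unclass(model$plan), flags = model$flags),
              params = lapply(ps, function(p) p$v),
              states = lapply(ss, function(s) list(rm = s$rm, rv = s$rv)))
  saveRDS(obj, path)
  invisible(path)
}

#' Restore a model saved with [save_checkpoint()]
#' @param path checkpoint file
#' @return a rebuilt `egaunet_model` with the stored weights
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "egaunet-checkpoint-1"))
    stop("not an egaunet checkpoint: ", path)
  plan <- obj$manifest$plan
  class(plan) <- "stage_plan"
  model <- build_egaunet(obj$manifest$num_classes, plan,
                         obj$manifest$in_channels,
                         use_gsca = obj$manifest$flags$use_gsca,
                         use_emcb = obj$manifest$flags$use_emcb,
                         gsca_skips_only = obj$manifest$flags$gsca_skips_only)
  restore_weights(model, obj)
  model
}

restore_weights <- function(model, obj) {
  ps <- all_params(model)
  if (!setequal(names(ps), names(obj$params)))
    stop("checkpoint parameter names do not match the rebuilt model")
  for (nm in names(ps)) ps[[nm]]$v <- obj$params[[nm]]
  ss <- all_states(model)
  for (nm in names(ss)) {
    ss[[nm]]$rm <- obj$states[[nm]]$rm
    ss[[nm]]$rv <- obj$states[[nm]]$rv
  }
  invisible(model)
}
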