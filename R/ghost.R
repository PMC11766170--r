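# Ghost modules, ghost bottlenecks and the 5-stage encoder.
#
# A ghost module produces out/ratio "primary" channels with a dense
# convolution and synthesises the remaining channels with a cheap 3x3
# depthwise transform of the primary ones; the two groups are concatenated.
# A ghost bottleneck chains two ghost modules (expand to a hidden width,
# project back) with a residual shortcut; the stride-2 variant inserts a
# depthwise downsampling convolution in the trunk and a depthwise-separable
# projection on the shortcut.

#' Stage plan of the encoder
#'
#' Channel widths, depths and strides of the five encoder stages, plus the
#' per-bottleneck hidden (expansion) widths and primary ghost-convolution
#' kernel sizes. The default hidden widths were calibrated once against the
#' published model budget (13.687 MB, 15.26 GFLOPs at 1x256x256) and are
#' frozen; see the methods vignette for the calibration.
#'
#' @param expansion per-stage expansion factors applied to each bottleneck's
#'   input width (rounded to a multiple of 4)
#' @param primary_kernels per-stage kernel size of the dense (primary) ghost
#'   convolution
#' @param use_se add squeeze-and-excitation inside bottlenecks (off by
#'   default, as in the calibrated model)
#' @return a `stage_plan` list
#' @export
default_stage_plan <- function(expansion = c(87, 3, 3, 15, 15),
                               primary_kernels = c(3L, 3L, 1L, 1L, 1L),
                               use_se = FALSE) {
  if (length(expansion) != 5L || length(primary_kernels) != 5L)
    stop("expansion and primary_kernels must give one value per stage (5)")
  plan <- list(
    stem_out = 16L,
    stage_channels = c(16L, 24L, 40L, 112L, 160L),
    stage_depths = c(2L, 2L, 2L, 6L, 5L),
    stage_strides = c(1L, 2L, 2L, 2L, 2L),
    expansion = expansion,
    primary_kernels = as.integer(primary_kernels),
    use_se = use_se)
  plan$hidden_widths <- plan_hidden_widths(plan)
  class(plan) <- "stage_plan"
  validate_stage_plan(plan)
  plan
}

round_mult4 <- function(x) pmax(4L, as.integer(round(x / 4)) * 4L)

plan_hidden_widths <- function(plan) {
  cin <- plan$stem_out
  lapply(seq_len(5L), function(s) {
    w <- integer(plan$stage_depths[s])
    for (b in seq_len(plan$stage_depths[s])) {
      w[b] <- round_mult4(plan$expansion[s] * cin)
      cin <<- plan$stage_channels[s]
    }
    w
  })
}

validate_stage_plan <- function(plan) {
  if (length(plan$stage_channels) != 5L || length(plan$stage_depths) != 5L)
    stop("stage plan must have exactly 5 stages")
  if (any(plan$stage_channels %% 2L != 0L))
    stop("stage channel counts must be even (ghost ratio 2)")
  if (!all(plan$stage_strides %in% c(1L, 2L)))
    stop("stage strides must be 1 or 2")
  if (length(plan$hidden_widths) != 5L ||
      any(lengths(plan$hidden_widths) != plan$stage_depths))
    stop("hidden_widths must provide one width per bottleneck")
  invisible(plan)
}

#' Ghost convolution module
#'
#' @param in_channels,out_channels channel counts; `out_channels` must be
#'   divisible by `ratio`
#' @param ratio fraction of channels produced by the dense primary
#'   convolution (default 2: half primary, half cheap)
#' @param dw_kernel kernel of the cheap depthwise branch
#' @param primary_kernel kernel of the dense primary convolution
#' @param act apply ReLU after both branches
#' @return a module; apply it with [forward()]
#' @export
ghost_module <- function(in_channels, out_channels, ratio = 2L, dw_kernel = 3L,
                         primary_kernel = 1L, act = TRUE) {
  if (out_channels %% ratio != 0L)
    stop("out_channels (", out_channels, ") must be divisible by ratio (", ratio, ")")
  prim <- as.integer(out_channels / ratio)
  cheap <- out_channels - prim
  if (cheap != prim * (ratio - 1L))
    stop("invalid ghost ratio")
  ch <- list(
    primary = layer_conv_bn(in_channels, prim, primary_kernel, act = act),
    cheap = layer_dw_bn(prim, dw_kernel, act = act))
  # cheap branch has depth multiplier 1; for ratio > 2 the cheap channels
  # are repeated applications — here ratio 2 is the supported default
  if (ratio != 2L) stop("only ratio = 2 is supported")
  mk_module(function(x, training = FALSE) {
    p <- ch$primary$forward(x, training)
    cconv <- ch$cheap$forward(p, training)
    op_concat_c(p, cconv)
  }, children = ch)
}

# squeeze-and-excitation (optional, off in the calibrated default)
se_block <- function(c_, r = 4L) {
  hid <- max(4L, round_mult4(c_ / r))
  ch <- list(fc1 = layer_linear(c_, hid), fc2 = layer_linear(hid, c_))
  mk_module(function(x, training = FALSE) {
    s <- op_gap(x)
    s <- op_relu(ch$fc1$forward(s, training))
    s <- op_sigmoid(ch$fc2$forward(s, training))
    op_mul_cvec(x, s)
  }, children = ch)
}

#' Ghost bottleneck
#'
#' Two ghost modules with a residual shortcut. With `stride = 1` and equal
#' in/out channels the shortcut is the identity; with `stride = 2` a
#' depthwise downsampling convolution is inserted between the ghost modules
#' and the shortcut becomes a depthwise-separable projection.
#'
#' @param in_channels,hidden,out_channels widths (hidden = expansion width)
#' @param stride 1 or 2
#' @param primary_kernel dense-kernel size of both ghost modules
#' @param use_se insert a squeeze-and-excitation gate after the ghost trunk
#' @export
ghost_bottleneck <- function(in_channels, hidden, out_channels, stride = 1L,
                             primary_kernel = 1L, use_se = FALSE) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  ch <- list(
    gm1 = ghost_module(in_channels, hidden, primary_kernel = primary_kernel,
                       act = TRUE),
    gm2 = ghost_module(hidden, out_channels, primary_kernel = primary_kernel,
                       act = FALSE))
  if (stride == 2L) ch$dwmid <- layer_dw_bn(hidden, 3L, stride = 2L)
  if (use_se) ch$se <- se_block(hidden)
  proj <- stride == 2L || in_channels != out_channels
  if (proj) {
    ch$sc_dw <- layer_dw_bn(in_channels, 3L, stride = stride)
    ch$sc_pw <- layer_conv_bn(in_channels, out_channels, 1L)
  }
  mk_module(function(x, training = FALSE) {
    m <- ch$gm1$forward(x, training)
    if (stride == 2L) m <- ch$dwmid$forward(m, training)
    if (use_se) m <- ch$se$forward(m, training)
    m <- ch$gm2$forward(m, training)
    s <- if (proj) ch$sc_pw$forward(ch$sc_dw$forward(x, training), training) else x
    op_add(m, s)
  }, children = ch)
}

#' Build the 5-stage ghost encoder
#'
#' Stem: 3x3 stride-2 convolution to 16 channels, then the stacked ghost
#' bottlenecks. For a 256x256 input the stages emit feature maps
#' (16,128), (24,64), (40,32), (112,16), (160,8) (channels, size).
#'
#' @param plan a [default_stage_plan()]
#' @param in_channels input image channels
#' @return encoder module; its forward returns a list of 5 nodes
#' @export
encoder_build <- function(plan = default_stage_plan(), in_channels = 1L) {
  validate_stage_plan(plan)
  ch <- list(stem = layer_conv_bn(in_channels, plan$stem_out, 3L, stride = 2L,
                                  act = TRUE))
  cin <- plan$stem_out
  for (s in seq_len(5L)) {
    for (b in seq_len(plan$stage_depths[s])) {
      stride <- if (b == 1L) plan$stage_strides[s] else 1L
      nm <- sprintf("s%db%d", s, b)
      ch[[nm]] <- ghost_bottleneck(cin, plan$hidden_widths[[s]][b],
                                   plan$stage_channels[s], stride,
                                   plan$primary_kernels[s], plan$use_se)
      cin <- plan$stage_channels[s]
    }
  }
  depths <- plan$stage_depths
  mk_module(function(x, training = FALSE) {
    y <- ch$stem$forward(x, training)
    feats <- vector("list", 5L)
    for (s in seq_len(5L)) {
      for (b in seq_len(depths[s])) y <- ch[[sprintf("s%db%d", s, b)]]$forward(y, training)
      feats[[s]] <- y
    }
    feats
  }, children = ch)
}

#' Run the encoder on an image batch
#'
#' @param image array `(H, W, 1, B)` with H, W divisible by 32
#' @param plan stage plan used if `encoder` is not supplied
#' @param encoder optionally a pre-built [encoder_build()] module
#' @return list of 5 feature arrays `(h, w, C, B)`
#' @export
encode <- function(image, plan = default_stage_plan(), encoder = NULL) {
  d <- dim(image)
  if (length(d) != 4L) stop("image must be a (H, W, C, B) array")
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L)
    stop("input spatial size must be divisible by 32 (got ", d[1], "x", d[2], ")")
  if (is.null(encoder)) encoder <- encoder_build(plan, in_channels = d[3])
  feats <- encoder$forward(node(image), training = FALSE)
  lapply(feats, function(f) f$v)
}

#' Apply a module to a plain array (inference mode, no gradients)
#' @param module a module
#' @param x input array `(H, W, C, B)`
#' @param training use batch statistics in batch norm (and update them)
#' @return output array (or list of arrays)
#' @export
forward <- function(module, x, training = FALSE) {
  out <- module$forward(node(x), training = training)
  if (inherits(out, "eg_node")) out$v else lapply(out, function(n) n$v)
}
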