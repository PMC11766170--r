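# Module infrastructure: a module is a list with named parameters, optional
# batch-norm state environments, child modules, and a forward closure taking
# a node plus training/profiling context. Parameter initialisation follows
# He (fan-in) scaling and consumes the R RNG stream in construction order,
# so a single set.seed() makes two builds bit-identical.

mk_module <- function(forward, params = list(), states = list(), children = list()) {
  structure(list(forward = forward, params = params, states = states,
                 children = children), class = "eg_module")
}

#' Collect all learnable parameters of a model
#' @param m a module (e.g. from [build_egaunet()])
#' @param prefix name prefix for the returned list
#' @return named list of parameter objects (environments with `$v`, `$g`)
#' @keywords internal
all_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params))
    out <- stats::setNames(m$params, paste0(prefix, names(m$params)))
  for (nm in names(m$children))
    out <- c(out, all_params(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

all_states <- function(m, prefix = "") {
  out <- list()
  if (length(m$states))
    out <- stats::setNames(m$states, paste0(prefix, names(m$states)))
  for (nm in names(m$children))
    out <- c(out, all_states(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

n_params <- function(m) sum(vapply(all_params(m), function(p) length(p$v), 0))

# ---- elementary layers -----------------------------------------------------

# conv2d + optional BN + optional ReLU. Convs followed by BN carry no bias.
layer_conv_bn <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                          bn = TRUE, act = FALSE, bias = !bn) {
  K <- k * k * cin   # weight stored (Cout x K)
  params <- list(w = new_param(matrix(stats::rnorm(cout * K, sd = sqrt(2 / K)), cout, K)))
  if (bias) params$b <- new_param(numeric(cout))
  states <- list()
  if (bn) {
    params$g <- new_param(rep(1, cout))
    params$be <- new_param(numeric(cout))
    st <- new.env(parent = emptyenv()); st$rm <- numeric(cout); st$rv <- rep(1, cout)
    states$bn <- st
  }
  force(k); force(stride); force(pad)
  mk_module(function(x, training = FALSE) {
    y <- op_conv2d(x, params$w, params$b, k, k, stride, pad)
    if (bn) y <- op_bn(y, params$g, params$be, states$bn, training)
    if (act) y <- op_relu(y)
    y
  }, params = params, states = states)
}

layer_dw_bn <- function(c_, k = 3L, stride = 1L, act = FALSE) {
  params <- list(
    w = new_param(array(stats::rnorm(k * k * c_, sd = sqrt(2 / (k * k))), c(k, k, c_))),
    g = new_param(rep(1, c_)),
    be = new_param(numeric(c_)))
  st <- new.env(parent = emptyenv()); st$rm <- numeric(c_); st$rv <- rep(1, c_)
  mk_module(function(x, training = FALSE) {
    y <- op_dwconv2d(x, params$w, k, k, stride, (k - 1L) %/% 2L)
    y <- op_bn(y, params$g, params$be, st, training)
    if (act) y <- op_relu(y)
    y
  }, params = params, states = list(bn = st))
}

layer_linear <- function(cin, cout, bias = TRUE) {
  params <- list(w = new_param(matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)),
                                      cout, cin)))
  if (bias) params$b <- new_param(numeric(cout))
  mk_module(function(x, training = FALSE) op_linear(x, params$w, params$b),
            params = params)
}

# ---- optimiser -------------------------------------------------------------

#' Adam optimiser state
#' @param params named list of parameters (from [all_params()])
#' @param lr learning rate
#' @param betas,eps usual Adam moment decay rates and stabiliser
#' @return an optimiser object; advance it with [adam_step()]
#' @export
adam <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$b1 <- betas[1]; st$b2 <- betas[2]; st$eps <- eps
  st$t <- 0L
  st$m <- lapply(params, function(p) 0 * p$v)
  st$u <- lapply(params, function(p) 0 * p$v)
  class(st) <- "eg_adam"
  st
}

#' Apply one Adam update using the gradients currently stored in the params
#' @param opt optimiser from [adam()]
#' @export
adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t; c2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * p$g
    opt$u[[i]] <- opt$b2 * opt$u[[i]] + (1 - opt$b2) * p$g^2
    p$v <- p$v - opt$lr * (opt$m[[i]] / c1) / (sqrt(opt$u[[i]] / c2) + opt$eps)
  }
  invisible(opt)
}
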