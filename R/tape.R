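#' @useDynLib egaunet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- reverse-mode autodiff over R arrays -----------------------------------
#
# Nodes are environments holding a value (`v`), an accumulated output
# gradient (`g`), a backward closure (`bk`) and the parent nodes it writes
# into. While a tape is recording, every op appends its node so that
# `tape_backward()` can sweep the tape in reverse creation order (a valid
# topological order). Outside a recording (inference) ops still return
# nodes but keep no parents, so intermediates are garbage-collected.

.eg <- new.env(parent = emptyenv())
.eg$recording <- FALSE
.eg$tape <- NULL
.eg$n <- 0L
.eg$profile <- NULL   # MAC counter (set by profile())

tape_start <- function() {
  .eg$recording <- TRUE
  .eg$tape <- vector("list", 4096L)
  .eg$n <- 0L
  invisible(NULL)
}

tape_stop <- function() {
  .eg$recording <- FALSE
  .eg$tape <- NULL
  .eg$n <- 0L
  invisible(NULL)
}

recording <- function() isTRUE(.eg$recording)

node <- function(v, parents = NULL, bk = NULL, pobj = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  if (recording()) {
    n$parents <- parents
    n$bk <- bk
    n$pobj <- pobj
    k <- .eg$n + 1L
    if (k > length(.eg$tape)) .eg$tape <- c(.eg$tape, vector("list", length(.eg$tape)))
    .eg$tape[[k]] <- n
    .eg$n <- k
  }
  class(n) <- "eg_node"
  n
}

as_node <- function(x) if (inherits(x, "eg_node")) x else node(x)

accum <- function(n, g) {
  if (is.null(n)) return(invisible(NULL))
  n$g <- if (is.null(n$g)) g else n$g + g
  invisible(NULL)
}

# Sweep the tape backwards from `loss` (a scalar node), accumulating
# gradients into parameter objects via their leaf nodes.
tape_backward <- function(loss) {
  stopifnot(recording())
  loss$g <- 1
  for (i in seq(.eg$n, 1L)) {
    n <- .eg$tape[[i]]
    if (is.null(n$g)) next
    if (!is.null(n$pobj)) n$pobj$g <- n$pobj$g + n$g
    if (!is.null(n$bk)) n$bk(n)
    # free memory early: grads of interior nodes are no longer needed
    if (i < .eg$n && !isTRUE(n$want_grad)) n$g <- NULL
  }
  invisible(NULL)
}

# ---- parameters ------------------------------------------------------------

new_param <- function(v, name = "") {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$g <- 0 * v
  p$name <- name
  class(p) <- "eg_param"
  p
}

# Leaf node bound to a parameter. `freeze = TRUE` detaches it (no gradient
# accumulation), used e.g. for the discriminator during generator updates.
leaf <- function(p, freeze = FALSE) {
  node(p$v, pobj = if (freeze) NULL else p)
}

zero_grads <- function(params) {
  for (p in params) p$g <- 0 * p$g
  invisible(NULL)
}

count_macs <- function(m) {
  if (!is.null(.eg$profile)) .eg$profile$macs <- .eg$profile$macs + m
  invisible(NULL)
}
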