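# Synthetic abdominal phantom generator. Each sample is a noisy background
# carrying up to four elliptical "organs" (liver, right kidney, left
# kidney, spleen) with class-specific mean intensities at anatomically
# plausible positions, plus the exact generating label mask. The phantoms
# stand in for abdominal T2 slices in every test; they reproduce the
# intensity-separable, few-blob structure of such data but none of its
# texture, partial-volume or multi-coil artefacts.

#' Phantom generator configuration
#'
#' Geometry is specified in fractions of the image size so phantoms scale
#' consistently; intensities are class means on the [0, 1] scale.
#'
#' @param n_samples number of image/mask pairs
#' @param image_size square image side (divisible by 32 for direct use with
#'   the network)
#' @param classes K including background
#' @param organs_range inclusive range of the number of organs per image
#' @param axis_frac per-class `(min, max)` ellipse semi-axis fractions,
#'   rows = foreground classes
#' @param centre_frac per-class `(row, col)` centre fractions
#' @param centre_jitter uniform jitter applied to the centres (fraction)
#' @param intensity per-class mean intensity, first entry = background
#' @param noise_sd Gaussian pixel noise standard deviation
#' @param force_classes fixed set of foreground classes to draw (overrides
#'   `organs_range`), e.g. `1L` for a single liver ellipse
#' @param seed RNG seed; the generator is fully reproducible
#' @export
phantom_config <- function(n_samples = 16L, image_size = 256L, classes = 5L,
                           organs_range = c(2L, 4L),
                           axis_frac = rbind(liver = c(0.14, 0.22),
                                             right_kidney = c(0.05, 0.09),
                                             left_kidney = c(0.05, 0.09),
                                             spleen = c(0.07, 0.12)),
                           centre_frac = rbind(liver = c(0.38, 0.34),
                                               right_kidney = c(0.62, 0.30),
                                               left_kidney = c(0.64, 0.62),
                                               spleen = c(0.40, 0.72)),
                           centre_jitter = 0.05,
                           intensity = c(0.15, 0.45, 0.62, 0.72, 0.85),
                           noise_sd = 0.05, force_classes = NULL, seed = 1L) {
  if (any(axis_frac <= 0)) stop("axis fractions must be positive")
  if (classes < 2L) stop("need at least one foreground class")
  cfg <- list(n_samples = as.integer(n_samples),
              image_size = as.integer(image_size), classes = as.integer(classes),
              organs_range = as.integer(organs_range), axis_frac = axis_frac,
              centre_frac = centre_frac, centre_jitter = centre_jitter,
              intensity = intensity, noise_sd = noise_sd,
              force_classes = force_classes, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

# rasterise a rotated ellipse: TRUE inside
ellipse_mask <- function(S, cy, cx, a, b, theta) {
  gy <- matrix(seq_len(S), S, S) - cy
  gx <- matrix(seq_len(S), S, S, byrow = TRUE) - cx
  u <- cos(theta) * gy + sin(theta) * gx
  v <- -sin(theta) * gy + cos(theta) * gx
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate synthetic phantom image/mask pairs
#'
#' Reproducible: the same config (seed included) yields identical samples.
#' Later classes overwrite earlier ones where ellipses overlap.
#'
#' @param config a [phantom_config()]
#' @return list of samples `list(image = (S,S,1) in [0,1], mask = (S,S)
#'   integer, source_id = character)`
#' @export
generate_phantoms <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  S <- config$image_size
  K <- config$classes
  nfg <- K - 1L
  out <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    if (is.null(config$force_classes)) {
      n_org <- sample(config$organs_range[1]:config$organs_range[2], 1L)
      present <- sort(sample(seq_len(nfg), min(n_org, nfg)))
    } else {
      present <- sort(as.integer(config$force_classes))
    }
    mask <- matrix(0L, S, S)
    img <- matrix(config$intensity[1], S, S)
    for (k in present) {
      ax <- stats::runif(1, config$axis_frac[k, 1], config$axis_frac[k, 2]) * S
      bx <- stats::runif(1, config$axis_frac[k, 1], config$axis_frac[k, 2]) * S
      cy <- (config$centre_frac[k, 1] +
               stats::runif(1, -config$centre_jitter, config$centre_jitter)) * S
      cx <- (config$centre_frac[k, 2] +
               stats::runif(1, -config$centre_jitter, config$centre_jitter)) * S
      th <- stats::runif(1, 0, pi)
      inside <- ellipse_mask(S, cy, cx, ax, bx, th)
      mask[inside] <- k
      img[inside] <- config$intensity[k + 1L]
    }
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(S * S, sd = config$noise_sd), S, S)
    img <- pmin(pmax(img, 0), 1)
    out[[i]] <- list(image = array(img, c(S, S, 1L)), mask = mask,
                     source_id = sprintf("phantom_%03d", i))
  }
  out
}
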