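# Multi-class segmentation evaluation: per-class confusion counts and the
# five indicators (Accuracy, Jaccard, Dice, Recall, Precision) in percent.
#
# Aggregation convention: counts are accumulated over the whole evaluation
# set, Jaccard/Dice/Recall/Precision are macro-averaged over the foreground
# classes (background excluded), and Accuracy is the overall pixel accuracy
# including background. A class absent from both truth and prediction
# scores 100 (perfect); a class absent from truth but predicted scores 0.

#' Per-class confusion counts
#'
#' @param pred,truth integer masks of equal shape with values in `[0, K)`
#' @param K number of classes
#' @return matrix K x 4 with columns TP, FP, FN, TN
#' @export
confusion_counts <- function(pred, truth, K) {
  if (!identical(dim(pred), dim(truth)) && length(pred) != length(truth))
    stop("pred and truth must have the same shape")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p >= K) || any(t < 0L | t >= K))
    stop("mask values must lie in [0, K)")
  joint <- tabulate(p * K + t + 1L, nbins = K * K)
  cm <- matrix(joint, K, K, byrow = TRUE)  # rows: predicted, cols: truth
  tp <- diag(cm)
  fp <- rowSums(cm) - tp
  fn <- colSums(cm) - tp
  tn <- length(p) - tp - fp - fn
  out <- cbind(TP = tp, FP = fp, FN = fn, TN = tn)
  rownames(out) <- paste0("class", seq_len(K) - 1L)
  out
}

#' Metric report from confusion counts
#'
#' @param counts matrix from [confusion_counts()] (possibly summed over
#'   many images)
#' @return a `metric_report`: `per_class` data.frame (percent) and
#'   `aggregate` named vector with Accuracy/Jaccard/Dice/Recall/Precision
#' @export
metric_report <- function(counts) {
  K <- nrow(counts)
  tp <- counts[, "TP"]; fp <- counts[, "FP"]; fn <- counts[, "FN"]
  rate <- function(num, den) {
    r <- ifelse(den > 0, num / den, 0)
    # class absent from truth and prediction: perfect by convention
    r[tp + fp + fn == 0] <- 1
    r
  }
  jac <- rate(tp, tp + fp + fn)
  dic <- rate(2 * tp, 2 * tp + fp + fn)
  rec <- rate(tp, tp + fn)
  pre <- rate(tp, tp + fp)
  # absent from truth but predicted: hallucination scores 0 everywhere
  halluc <- (tp + fn == 0) & (fp > 0)
  jac[halluc] <- 0; dic[halluc] <- 0; rec[halluc] <- 0; pre[halluc] <- 0
  total <- sum(counts[1, ])
  acc <- sum(tp) / total
  per_class <- data.frame(class = seq_len(K) - 1L,
                          Jaccard = 100 * jac, Dice = 100 * dic,
                          Recall = 100 * rec, Precision = 100 * pre,
                          row.names = NULL)
  fg <- seq_len(K)[-1L]
  aggregate <- c(Accuracy = 100 * acc,
                 Jaccard = mean(100 * jac[fg]),
                 Dice = mean(100 * dic[fg]),
                 Recall = mean(100 * rec[fg]),
                 Precision = mean(100 * pre[fg]))
  structure(list(per_class = per_class, aggregate = aggregate, counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("per class (%):\n")
  print(x$per_class, digits = 4)
  cat("\naggregate (macro over foreground; accuracy incl. background):\n")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Evaluate predicted masks against ground truth
#'
#' @param preds,truths integer arrays `(H, W, B)` (or lists of 2-D masks)
#' @param K class count
#' @param per_image average per-image reports instead of accumulating
#'   counts over the whole set
#' @return a `metric_report` (for `per_image = TRUE` the aggregate is the
#'   mean of per-image aggregates)
#' @export
evaluate_masks <- function(preds, truths, K, per_image = FALSE) {
  if (is.array(preds) && length(dim(preds)) == 3L) {
    preds <- lapply(seq_len(dim(preds)[3]), function(i) preds[, , i])
    truths <- lapply(seq_len(dim(truths)[3]), function(i) truths[, , i])
  }
  if (!per_image) {
    counts <- Reduce(`+`, Map(function(p, t) confusion_counts(p, t, K),
                              preds, truths))
    return(metric_report(counts))
  }
  reps <- Map(function(p, t) metric_report(confusion_counts(p, t, K)),
              preds, truths)
  agg <- Reduce(`+`, lapply(reps, `[[`, "aggregate")) / length(reps)
  structure(list(per_class = NULL, aggregate = agg,
                 counts = Reduce(`+`, lapply(reps, `[[`, "counts"))),
            class = "metric_report")
}

#' Export a metric report as CSV (one row per class plus aggregate)
#' @param report a `metric_report`
#' @param path output file
#' @export
write_metrics_csv <- function(report, path) {
  pc <- report$per_class
  agg <- data.frame(class = "aggregate",
                    Jaccard = report$aggregate[["Jaccard"]],
                    Dice = report$aggregate[["Dice"]],
                    Recall = report$aggregate[["Recall"]],
                    Precision = report$aggregate[["Precision"]])
  if (!is.null(pc)) {
    pc$class <- as.character(pc$class)
    agg <- rbind(pc, agg)
  }
  agg$Accuracy <- c(rep(NA, nrow(agg) - 1L), report$aggregate[["Accuracy"]])
  utils::write.csv(agg, path, row.names = FALSE)
  invisible(path)
}

#' Evaluate a model on a dataset
#'
#' Deterministic: eval-mode prediction on each sample, counts accumulated
#' over the whole set.
#'
#' @param model an `egaunet_model`
#' @param data list of `list(image, mask)` samples
#' @param batch_size images per forward pass
#' @inheritParams evaluate_masks
#' @return a `metric_report`
#' @export
evaluate_model <- function(model, data, batch_size = 4L, per_image = FALSE) {
  if (!length(data)) stop("empty evaluation data")
  preds <- list(); truths <- list()
  i <- 1L
  while (i <= length(data)) {
    idx <- i:min(i + batch_size - 1L, length(data))
    bat <- stack_batch(data, idx, augment = FALSE)
    lab <- predict_labels(model, bat$x)
    for (j in seq_along(idx)) {
      preds[[idx[j]]] <- lab[, , j]
      truths[[idx[j]]] <- bat$y[, , j]
    }
    i <- i + batch_size
  }
  evaluate_masks(preds, truths, model$num_classes, per_image = per_image)
}
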