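# Training objective and evaluation metrics.
#
# Loss = soft Dice + 0.5 * binary cross-entropy on the predicted foreground
# probabilities. Dice uses a smoothing constant of 1 in numerator and
# denominator; BCE clips probabilities at 1e-7 for numerical stability.
# Metrics are exact ratios of pooled pixel confusion counts:
#   IoU = TP / (TP + FP + FN),        recall    = TP / (TP + FN),
#   F1  = 2 TP / (2 TP + FP + FN),    precision = TP / (TP + FP).

DICE_EPS <- 1
BCE_CLIP <- 1e-7

#' Compound Dice + BCE segmentation loss
#'
#' @param pred probability array in `[0, 1]`.
#' @param target binary array of the same shape.
#' @param gradient also return the gradient with respect to `pred`.
#' @return the scalar loss, or (with `gradient = TRUE`) a list with
#'   `loss` and `grad`.
#' @export
dice_bce_loss <- function(pred, target, gradient = FALSE) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target shapes differ")
  p <- pmin(pmax(pred, BCE_CLIP), 1 - BCE_CLIP)
  n <- length(p)
  inter <- sum(p * target)
  tot <- sum(p) + sum(target)
  dice <- 1 - (2 * inter + DICE_EPS) / (tot + DICE_EPS)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  loss <- dice + 0.5 * bce
  if (!gradient) return(loss)
  # d dice / d p = -(2 t (tot+eps) - (2 inter + eps)) / (tot+eps)^2
  ddice <- -(2 * target * (tot + DICE_EPS) - (2 * inter + DICE_EPS)) /
    (tot + DICE_EPS)^2
  dbce <- (-target / p + (1 - target) / (1 - p)) / n
  g <- ddice + 0.5 * dbce
  g[pred <= BCE_CLIP & g > 0] <- 0              # clipped region: flat
  g[pred >= 1 - BCE_CLIP & g < 0] <- 0
  list(loss = loss, grad = array(g, dim = dim(pred)))
}

#' Pixel confusion counts
#'
#' Thresholds the probability map and tallies true/false positives and
#' negatives over all supplied pixels (global aggregation).
#'
#' @param pred probability array.
#' @param target binary array of the same shape.
#' @param threshold binarisation threshold for `pred`.
#' @return a list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, target, threshold = 0.5) {
  if (length(pred) != length(target))
    stop("pred and target shapes differ")
  ph <- pred >= threshold
  th <- target >= 0.5
  structure(list(tp = sum(ph & th), fp = sum(ph & !th),
                 fn = sum(!ph & th), tn = sum(!ph & !th)),
            class = "confusion_counts")
}

#' Combine confusion counts
#'
#' @param ... `confusion_counts` objects.
#' @return their elementwise sum.
#' @export
combine_counts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && is.list(cs[[1]]) &&
      !inherits(cs[[1]], "confusion_counts")) cs <- cs[[1]]
  structure(list(tp = sum(vapply(cs, `[[`, 0, "tp")),
                 fp = sum(vapply(cs, `[[`, 0, "fp")),
                 fn = sum(vapply(cs, `[[`, 0, "fn")),
                 tn = sum(vapply(cs, `[[`, 0, "tn"))),
            class = "confusion_counts")
}

safe_ratio <- function(num, den, both_empty) {
  if (den == 0) return(if (both_empty) 1 else 0)
  num / den
}

#' Overlap metrics from confusion counts
#'
#' Exact IoU, recall, precision and F1 ratios. Degenerate 0/0 cases return
#' 1 when both the ground truth and the prediction are empty (a perfect
#' match of nothing) and 0 otherwise.
#'
#' @param counts a `confusion_counts` object.
#' @return a list of class `metric_set` with fields `iou`, `recall`,
#'   `precision`, `f1`, each in `[0, 1]`.
#' @export
seg_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn, counts$tn) < 0)) stop("negative counts")
  empty <- tp + fn == 0 && tp + fp == 0
  structure(list(
    iou = safe_ratio(tp, tp + fp + fn, empty),
    recall = safe_ratio(tp, tp + fn, empty),
    precision = safe_ratio(tp, tp + fp, empty),
    f1 = safe_ratio(2 * tp, 2 * tp + fp + fn, empty)),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("IoU %.2f%%  recall %.2f%%  precision %.2f%%  F1 %.2f%%\n",
              100 * x$iou, 100 * x$recall, 100 * x$precision, 100 * x$f1))
  invisible(x)
}

#' Evaluate predictions against masks
#'
#' @param preds list of probability arrays (or one array).
#' @param targets list of matching binary masks.
#' @param threshold binarisation threshold.
#' @param per_image also compute per-image metric rows.
#' @return a `metric_set` from globally pooled counts; with
#'   `per_image = TRUE`, a list with `global` and a per-image data.frame.
#' @export
evaluate_predictions <- function(preds, targets, threshold = 0.5,
                                 per_image = FALSE) {
  if (!is.list(preds)) { preds <- list(preds); targets <- list(targets) }
  if (length(preds) == 0L) stop("empty evaluation set")
  if (length(preds) != length(targets))
    stop("prediction/target count mismatch")
  cs <- Map(confusion_counts, preds, targets,
            MoreArgs = list(threshold = threshold))
  g <- seg_metrics(combine_counts(cs))
  if (!per_image) return(g)
  rows <- do.call(rbind, lapply(seq_along(cs), function(i) {
    m <- seg_metrics(cs[[i]])
    data.frame(image = i, iou = m$iou, recall = m$recall,
               precision = m$precision, f1 = m$f1)
  }))
  list(global = g, per_image = rows)
}
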