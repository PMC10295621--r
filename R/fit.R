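# Model-fitting front end in the classic R idiom: one fitting function
# returning a classed object with print/summary/coef/predict/plot/residuals
# methods. The heavy lifting lives in network.R and pipeline.R.

#' Fit the segmentation network
#'
#' Trains a segmentation model on a set of image/mask samples and returns a
#' fitted-model object. `data` is either a list of samples (as produced by
#' [generate_dataset()] or [load_folder()]) or a path to an
#' `images/` + `masks/` folder. A fraction of the training data can be held
#' out as a validation set that drives best-checkpoint selection.
#'
#' @param data samples or folder path.
#' @param variant architecture variant, see [build_variant()].
#' @param epochs,batch_size,lr0,lr_power,weight_decay,seed,augment,max_steps
#'   training settings, see [train_config()].
#' @param val_frac fraction of `data` held out for validation (0 disables).
#' @param se_reduction SE ratio of the LDA-B stages.
#' @param verbose print per-epoch progress.
#' @return an object of class `lcmunet_fit`.
#' @export
lcmunet <- function(data, variant = "lcmunet", epochs = 100L,
                    batch_size = 8L, lr0 = 1e-3, lr_power = 0.9,
                    weight_decay = 5e-4, seed = 1L, val_frac = 0.125,
                    se_reduction = 2L, augment = TRUE, max_steps = NULL,
                    verbose = FALSE) {
  if (is.character(data)) data <- load_folder(data)
  stopifnot(is.list(data), length(data) >= 1)
  cfg <- train_config(epochs = epochs, batch_size = batch_size, lr0 = lr0,
                      lr_power = lr_power, weight_decay = weight_decay,
                      seed = seed, variant = variant,
                      se_reduction = se_reduction, augment = augment,
                      max_steps = max_steps)
  set.seed(cfg$seed)
  model <- build_variant(variant, se_reduction = se_reduction)
  if (val_frac > 0 && length(data) >= 8L) {
    sp <- split_samples(data, train_frac = 1 - val_frac, seed = seed)
    train <- sp$train; val <- sp$test
  } else {
    train <- data; val <- NULL
  }
  res <- train_model(model, train, cfg, val_samples = val,
                     verbose = verbose)
  set_state(model, res$best_state)
  structure(list(model = model, config = cfg, history = res$history,
                 n_train = length(train),
                 n_val = if (is.null(val)) 0L else length(val),
                 best_val_iou = res$best_iou, steps = res$steps,
                 train_metrics = evaluate_model(model, train)),
            class = "lcmunet_fit")
}

#' @export
print.lcmunet_fit <- function(x, ...) {
  cat("Fitted segmentation network\n")
  cat(sprintf("  variant: %s  (%.2f M parameters)\n",
              x$config$variant, count_parameters(x$model) / 1e6))
  cat(sprintf("  trained: %d steps on %d samples (%d validation)\n",
              x$steps, x$n_train, x$n_val))
  cat(sprintf("  training IoU %.3f", x$train_metrics$iou))
  if (is.finite(x$best_val_iou))
    cat(sprintf("  best validation IoU %.3f", x$best_val_iou))
  cat("\n")
  invisible(x)
}

#' @export
summary.lcmunet_fit <- function(object, ...) {
  r <- complexity_report(object$model)
  cat(sprintf("Variant %s: %s parameters (%.2f M), %.3f GFLOPs at %dx%d\n",
              r$variant, format(r$params, big.mark = ","), r$params_M,
              r$gflops, r$input_size[1], r$input_size[2]))
  m <- object$train_metrics
  cat(sprintf(
    "Training metrics: IoU %.2f%%, recall %.2f%%, precision %.2f%%, F1 %.2f%%\n",
    100 * m$iou, 100 * m$recall, 100 * m$precision, 100 * m$f1))
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("Loss %.4f -> %.4f over %d epochs (lr %.1e -> %.1e)\n",
                h$loss[1], h$loss[nrow(h)], nrow(h), h$lr[1],
                h$lr[nrow(h)]))
  }
  invisible(object)
}

#' @export
coef.lcmunet_fit <- function(object, ...) {
  st <- get_state(object$model)
  params <- unlist(lapply(st, function(s) s$params), recursive = FALSE)
  attr(params, "n_parameters") <- count_parameters(object$model)
  params
}

#' Predict segmentation masks
#'
#' @param object a fitted model.
#' @param newdata a list of samples, one sample, or a `(3, H, W[, N])`
#'   image array.
#' @param type `"prob"` for probability maps, `"mask"` for binary masks.
#' @param threshold binarisation threshold for `type = "mask"`.
#' @param ... unused.
#' @return a list of `(1, H, W)` arrays (or a single array for one input).
#' @export
predict.lcmunet_fit <- function(object, newdata, type = c("prob", "mask"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  single <- FALSE
  if (is.array(newdata) && length(dim(newdata)) %in% c(3L, 4L)) {
    if (length(dim(newdata)) == 3L) {
      newdata <- list(list(image = newdata)); single <- TRUE
    } else {
      newdata <- lapply(seq_len(dim(newdata)[4]), function(i)
        list(image = newdata[, , , i]))
    }
  } else if (is.list(newdata) && !is.null(newdata$image)) {
    newdata <- list(newdata); single <- TRUE
  }
  out <- lapply(newdata, function(s) {
    x <- array(s$image, dim = c(dim(s$image)[1:3], 1L))
    p <- model_forward(object$model, x, training = FALSE)
    p <- array(p, dim = dim(p)[1:3])
    if (type == "mask") array(as.double(p >= threshold), dim = dim(p))
    else p
  })
  if (single) out[[1]] else out
}

#' Residual maps
#'
#' @param object a fitted model.
#' @param data samples with masks (defaults give an error; supply the set
#'   you want residuals for).
#' @param ... unused.
#' @return list of `(1, H, W)` arrays of `mask - predicted probability`.
#' @export
residuals.lcmunet_fit <- function(object, data, ...) {
  preds <- predict(object, data)
  if (!is.list(preds) || !is.null(dim(preds))) preds <- list(preds)
  Map(function(s, p) s$mask - p, data, preds)
}

#' Plot training history
#'
#' Loss (and validation IoU when present) against epoch.
#'
#' @param x a fitted model.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics lines legend par axis mtext
#' @export
plot.lcmunet_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("no training history recorded")
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(h$epoch, h$loss, type = "l", lwd = 2, xlab = "epoch",
       ylab = "training loss", ...)
  if (any(is.finite(h$val_iou))) {
    par(new = TRUE)
    plot(h$epoch, h$val_iou, type = "l", lty = 2, col = "grey40",
         axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    axis(4)
    mtext("validation IoU", side = 4, line = 2.5)
    legend("right", legend = c("loss", "val IoU"), lty = c(1, 2),
           col = c("black", "grey40"), bty = "n")
  }
  invisible(x)
}
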