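# Training and evaluation orchestration.
#
# Training follows the published recipe: Adam, initial learning rate 1e-3,
# polynomial decay with power 0.9 stepped per iteration, weight decay 5e-4
# (classic L2-in-gradient coupling), batch size 8, Dice + 0.5 BCE loss,
# online augmentation. Checkpoints carry a structural fingerprint and are
# refused when it does not match the built model.

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size images per optimisation step.
#' @param lr0 initial learning rate.
#' @param lr_power power of the polynomial decay schedule.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param seed integer seed controlling initialisation, data order and
#'   augmentation.
#' @param variant model variant to train.
#' @param se_reduction SE ratio for the LDA-B stages.
#' @param augment apply online augmentation to training batches.
#' @param max_steps optional hard cap on optimisation steps.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 8L, lr0 = 1e-3,
                         lr_power = 0.9, weight_decay = 5e-4, seed = 1L,
                         variant = "lcmunet", se_reduction = 2L,
                         augment = TRUE, max_steps = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0,
            lr_power > 0, lr_power <= 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 lr_power = lr_power, weight_decay = weight_decay,
                 seed = as.integer(seed), variant = variant,
                 se_reduction = as.integer(se_reduction),
                 augment = isTRUE(augment),
                 max_steps = if (is.null(max_steps)) NULL else
                   as.integer(max_steps)),
            class = "train_config")
}

#' Polynomial learning-rate schedule
#'
#' `lr0 * (1 - iter/max_iter)^power`.
#'
#' @param iter current iteration, `0 <= iter <= max_iter`.
#' @param max_iter total iterations.
#' @param lr0 initial learning rate.
#' @param power decay power.
#' @return the learning rate at `iter`.
#' @export
poly_lr <- function(iter, max_iter, lr0 = 1e-3, power = 0.9) {
  stopifnot(iter >= 0, iter <= max_iter, max_iter > 0)
  lr0 * (1 - iter / max_iter)^power
}

# Adam with coupled weight decay; moment state lives on each layer.
adam_step <- function(layers, lr, weight_decay, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$grads)) next
    if (is.null(l$opt)) l$opt <- list(m = list(), v = list())
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * l$params[[nm]]
      m <- l$opt$m[[nm]]; v <- l$opt$v[[nm]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mh / (sqrt(vh) + eps)
      l$opt$m[[nm]] <- m; l$opt$v[[nm]] <- v
    }
    l$grads <- NULL
  }
}

stack_batch <- function(samples, field = "image") {
  d <- dim(samples[[1]][[field]])
  out <- array(0, dim = c(d, length(samples)))
  for (i in seq_along(samples)) out[, , , i] <- samples[[i]][[field]]
  out
}

# model state (weights + norm statistics) as a plain list
get_state <- function(model) {
  lapply(collect_layers(model), function(l)
    list(params = l$params, running_mean = l$running_mean,
         running_var = l$running_var))
}

set_state <- function(model, state) {
  layers <- collect_layers(model)
  if (length(layers) != length(state))
    stop("state does not match model structure")
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!identical(lapply(l$params, dim), lapply(state[[i]]$params, dim)))
      stop("state does not match model structure at layer ", i)
    l$params <- state[[i]]$params
    if (!is.null(state[[i]]$running_mean)) {
      l$running_mean <- state[[i]]$running_mean
      l$running_var <- state[[i]]$running_var
    }
  }
  invisible(model)
}

#' Train a model
#'
#' Runs the optimisation loop on a list of training samples, tracking the
#' loss, learning rate and (when a validation set is supplied) validation
#' IoU per epoch; the returned state is the best-validation-IoU weights
#' (or the final weights without validation).
#'
#' @param model a built model (its weights are updated in place).
#' @param train_samples list of training samples.
#' @param cfg a [train_config()].
#' @param val_samples optional validation samples driving best-checkpoint
#'   selection.
#' @param verbose print per-epoch progress.
#' @return a list with `history` (data.frame: epoch, loss, lr, val_iou),
#'   `best_state`, `best_iou`, `steps`.
#' @export
train_model <- function(model, train_samples, cfg, val_samples = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(train_samples) >= 1)
  set.seed(cfg$seed)
  layers <- collect_layers(model)
  n <- length(train_samples)
  batches_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  max_iter <- if (!is.null(cfg$max_steps)) cfg$max_steps else
    cfg$epochs * batches_per_epoch
  hist <- list()
  step <- 0L
  best_iou <- -Inf
  best_state <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    epoch_loss <- 0
    nb <- 0L
    epoch_lr <- poly_lr(step, max_iter, cfg$lr0, cfg$lr_power)
    for (b in seq_len(batches_per_epoch)) {
      if (step >= max_iter) break
      take <- idx[seq.int((b - 1L) * cfg$batch_size + 1L,
                          min(b * cfg$batch_size, n))]
      batch <- train_samples[take]
      if (cfg$augment) batch <- lapply(batch, augment)
      x <- stack_batch(batch, "image")
      y <- stack_batch(batch, "mask")
      lr <- poly_lr(step, max_iter, cfg$lr0, cfg$lr_power)
      p <- model_forward(model, x, training = TRUE)
      lg <- dice_bce_loss(p, y, gradient = TRUE)
      if (!is.finite(lg$loss))
        stop("training diverged: non-finite loss at step ", step)
      model_backward(model, lg$grad)
      step <- step + 1L
      adam_step(layers, lr, cfg$weight_decay, step)
      epoch_loss <- epoch_loss + lg$loss
      nb <- nb + 1L
    }
    if (nb == 0L) break
    val_iou <- NA_real_
    if (!is.null(val_samples) && length(val_samples)) {
      val_iou <- evaluate_model(model, val_samples)$iou
      if (val_iou >= best_iou) {
        best_iou <- val_iou
        best_state <- get_state(model)
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, loss = epoch_loss / nb,
                                lr = epoch_lr, val_iou = val_iou)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  lr %.2e  val IoU %s",
                      epoch, epoch_loss / nb, epoch_lr,
                      ifelse(is.na(val_iou), "-",
                             sprintf("%.3f", val_iou))))
    if (step >= max_iter) break
  }
  if (is.null(best_state)) {
    best_state <- get_state(model)
    best_iou <- NA_real_
  }
  list(history = do.call(rbind, hist), best_state = best_state,
       best_iou = best_iou, steps = step)
}

#' Evaluate a model on samples
#'
#' Deterministic evaluation-mode forward pass; confusion counts are pooled
#' globally over all pixels before computing metrics (per-image rows
#' optionally included). No augmentation is applied.
#'
#' @param model a built (or trained) model.
#' @param samples non-empty list of samples.
#' @param threshold binarisation threshold.
#' @param per_image include a per-image metric table.
#' @param batch_size evaluation batch size.
#' @return a `metric_set`, or a list with `global` and `per_image`.
#' @export
evaluate_model <- function(model, samples, threshold = 0.5,
                           per_image = FALSE, batch_size = 8L) {
  if (!length(samples)) stop("empty evaluation set")
  preds <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    take <- seq.int(i, min(i + batch_size - 1L, length(samples)))
    x <- stack_batch(samples[take], "image")
    p <- model_forward(model, x, training = FALSE)
    for (j in seq_along(take))
      preds[[take[j]]] <- p[, , , j, drop = FALSE]
    i <- i + batch_size
  }
  targets <- lapply(samples, `[[`, "mask")
  preds1 <- lapply(preds, function(p) array(p, dim = dim(p)[1:3]))
  evaluate_predictions(preds1, targets, threshold, per_image)
}

# checkpoints -------------------------------------------------------------------

#' Save a model checkpoint
#'
#' @param model the model.
#' @param path file path (`.rds`).
#' @param history optional training history to embed.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  saveRDS(list(variant = model$variant,
               se_reduction = model$se_reduction,
               fingerprint = model_fingerprint(model),
               state = get_state(model), history = history), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the stored variant and restores its weights; refuses a
#' checkpoint whose structural fingerprint does not match.
#'
#' @param path file path written by [save_checkpoint()].
#' @return the restored model (attribute `history` carries the stored
#'   training history).
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_variant(ck$variant, se_reduction = ck$se_reduction %||% 2L)
  set_state(model, ck$state)
  if (!identical(model_fingerprint(model), ck$fingerprint))
    stop("checkpoint fingerprint mismatch: expected ", ck$fingerprint,
         ", built ", model_fingerprint(model))
  attr(model, "history") <- ck$history
  model
}
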