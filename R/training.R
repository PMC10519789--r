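# Training loop: Adam, linear warmup followed by exponential learning-rate
# decay, cross-entropy loss, epoch-level history, best-validation checkpoint.

#' Training configuration
#'
#' Defaults are the published recipe: Adam, base learning rate 0.001, 200
#' epochs with 20 warmup epochs, exponential decay factor 0.99 per epoch,
#' batch size 32.
#'
#' @param base_lr peak learning rate reached at the end of warmup.
#' @param epochs total training epochs.
#' @param warmup_epochs epochs of linear warmup (must be < `epochs`).
#' @param gamma per-epoch exponential decay factor after warmup, in (0, 1].
#' @param batch_size minibatch size.
#' @param seed seed controlling initialization order, shuffling, augmentation
#'   and stochastic regularization.
#' @return a `train_config` object.
#' @export
train_config <- function(base_lr = 0.001, epochs = 200L, warmup_epochs = 20L,
                         gamma = 0.99, batch_size = 32L, seed = 1L) {
  if (warmup_epochs >= epochs) abort("warmup_epochs must be < epochs")
  if (gamma <= 0 || gamma > 1) abort("gamma must be in (0, 1]")
  structure(list(optimizer = "adam", base_lr = base_lr,
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs), gamma = gamma,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warmup from `base_lr / warmup_epochs` at epoch 0 up to `base_lr` at
#' the end of warmup, then `base_lr * gamma^(epoch - warmup_epochs)`.
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`.
#' @param cfg a [train_config()].
#' @return learning rate (numeric).
#' @export
lr_at <- function(epoch, cfg) {
  if (any(epoch < 0) || any(epoch >= cfg$epochs))
    abort("epoch out of range [0, epochs)")
  ifelse(epoch < cfg$warmup_epochs,
         cfg$base_lr * (epoch + 1) / cfg$warmup_epochs,
         cfg$base_lr * cfg$gamma^(epoch - cfg$warmup_epochs))
}

adam_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) array(0, dim = dim(p$v)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$v)))
  st$t <- 0L
  st
}

adam_step <- function(params, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * p$grad
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * p$grad^2
    p$v <- p$v - lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  invisible(NULL)
}

snapshot_params <- function(model) {
  lapply(model_param_list(model), function(p) p$v)
}

restore_params <- function(model, snap) {
  params <- model_param_list(model)
  for (i in seq_along(params)) params[[i]]$v <- snap[[i]]
  invisible(model)
}

snapshot_running <- function(model) {
  out <- list()
  walk <- function(mod, prefix) {
    if (mod$type == "norm" && mod$cfg$mode == "BN")
      out[[prefix]] <<- list(mean = mod$cfg$running$mean, var = mod$cfg$running$var)
    for (nm in names(mod$children)) walk(mod$children[[nm]], paste0(prefix, nm, "."))
  }
  for (nm in names(model$children)) walk(model$children[[nm]], paste0(nm, "."))
  out
}

restore_running <- function(model, snap) {
  walk <- function(mod, prefix) {
    if (mod$type == "norm" && mod$cfg$mode == "BN" && !is.null(snap[[prefix]])) {
      mod$cfg$running$mean <- snap[[prefix]]$mean
      mod$cfg$running$var <- snap[[prefix]]$var
    }
    for (nm in names(mod$children)) walk(mod$children[[nm]], paste0(prefix, nm, "."))
  }
  for (nm in names(model$children)) walk(model$children[[nm]], paste0(nm, "."))
  invisible(model)
}

#' Evaluate a model on a labelled image set
#'
#' @param model an `fcaenet_model`.
#' @param x array `(H, W, 3, N)`.
#' @param y integer labels (1-based).
#' @param batch_size evaluation batch size.
#' @return list with `loss`, `accuracy`, and integer predictions `pred`.
#' @export
evaluate_model <- function(model, x, y, batch_size = 32L) {
  n <- dim(x)[4]
  losses <- numeric(0); preds <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- forward_model(model, x[, , , idx, drop = FALSE], training = FALSE)
    loss <- op_softmax_xent(out$logits, y[idx])
    losses <- c(losses, loss$v * length(idx))
    preds[idx] <- apply(loss$probs, 2, which.max)
  }
  list(loss = sum(losses) / n, accuracy = mean(preds == y), pred = preds)
}

#' Train a model
#'
#' Runs the warmup + exponential-decay schedule with Adam and cross-entropy,
#' logging one history row per epoch and keeping the parameters of the best
#' validation-accuracy epoch.  All randomness (shuffling, online
#' augmentation, dropout, stochastic depth) is derived from `cfg$seed`, so a
#' rerun with the same inputs is identical.
#'
#' @param model an `fcaenet_model` (modified in place and returned in the fit).
#' @param train_data,valid_data lists with `x` (array `(H, W, 3, N)`) and `y`
#'   (1-based integer labels).
#' @param cfg a [train_config()].
#' @param augment optional per-image augmentation `function(img)` applied to
#'   training images each epoch (see [augment_online()]); `NULL` disables.
#' @param stop_at_val_acc optional early-stop threshold on validation accuracy.
#' @param verbose print one line per epoch to stderr.
#' @return an `fcaenet_fit`: the model (restored to its best-validation
#'   parameters), a `history` tibble (epoch, lr, train/valid loss and
#'   accuracy), and the best epoch index.
#' @export
train <- function(model, train_data, valid_data, cfg, augment = NULL,
                  stop_at_val_acc = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "train_config"))
  n <- dim(train_data$x)[4]
  if (n < 1L || dim(valid_data$x)[4] < 1L) abort("datasets must be non-empty")
  if (max(train_data$y, valid_data$y) > model$spec$num_classes)
    abort("labels exceed the model's class count")
  set.seed(cfg$seed)
  params <- model_param_list(model)
  st <- adam_state(params)
  history <- list()
  best_acc <- -Inf; best_snap <- NULL; best_running <- NULL; best_epoch <- NA_integer_
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- lr_at(epoch, cfg)
    order <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- order[start:min(start + cfg$batch_size - 1L, n)]
      xb <- train_data$x[, , , idx, drop = FALSE]
      if (!is.null(augment))
        for (j in seq_along(idx)) xb[, , , j] <- augment(xb[, , , j])
      yb <- train_data$y[idx]
      rec <- ag_with_tape({
        out <- forward_model(model, xb, training = TRUE)
        op_softmax_xent(out$logits, yb)
      })
      loss <- rec$value
      if (!is.finite(loss$v))
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      ag_zero_grad(params)
      ag_backward(loss, rec$tape)
      adam_step(params, st, lr)
      ep_loss <- ep_loss + loss$v * length(idx)
      ep_correct <- ep_correct + sum(apply(loss$probs, 2, which.max) == yb)
    }
    val <- evaluate_model(model, valid_data$x, valid_data$y, cfg$batch_size)
    history[[length(history) + 1L]] <- tibble::tibble(
      epoch = epoch, lr = lr,
      train_loss = ep_loss / n, train_acc = ep_correct / n,
      valid_loss = val$loss, valid_acc = val$accuracy)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train loss %.4f acc %.3f  valid loss %.4f acc %.3f",
                      epoch, lr, ep_loss / n, ep_correct / n, val$loss, val$accuracy))
    if (val$accuracy > best_acc) {
      best_acc <- val$accuracy; best_snap <- snapshot_params(model)
      best_running <- snapshot_running(model); best_epoch <- epoch
    }
    if (!is.null(stop_at_val_acc) && val$accuracy >= stop_at_val_acc) break
  }
  restore_params(model, best_snap)
  restore_running(model, best_running)
  structure(list(model = model, history = dplyr::bind_rows(history),
                 cfg = cfg, best_epoch = best_epoch,
                 best_valid_acc = best_acc),
            class = "fcaenet_fit")
}

#' @export
print.fcaenet_fit <- function(x, ...) {
  cat(sprintf("<fcaenet_fit> %d epochs, best valid accuracy %.3f at epoch %d\n",
              nrow(x$history), x$best_valid_acc, x$best_epoch))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Serializes the architecture spec, build seed, all parameter values and BN
#' running statistics with R's native serialization; loading rebuilds the
#' model and restores them, so a round trip reproduces validation metrics
#' exactly.
#'
#' @param model an `fcaenet_model` or `fcaenet_fit`.
#' @param path file path (`.rds`).
#' @return `load_model()` returns the rebuilt `fcaenet_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "fcaenet_fit")) model <- model$model
  saveRDS(list(spec = model$spec, seed = model$seed,
               params = snapshot_params(model),
               running = snapshot_running(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$spec, seed = obj$seed)
  restore_params(model, obj$params)
  restore_running(model, obj$running)
  model
}
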