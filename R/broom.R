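# broom-style tidiers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a metrics report
#'
#' @param x a `metrics_report` from [compute_metrics()].
#' @param ... unused.
#' @return per-class tibble of counts and metrics.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1,
                 n = x$total)
}

#' Tidy a built model
#'
#' @param x an `fcaenet_model`.
#' @param ... unused.
#' @return the per-stage summary tibble of [model_summary()].
#' @export
tidy.fcaenet_model <- function(x, ...) model_summary(x)

#' @rdname tidy.fcaenet_model
#' @export
glance.fcaenet_model <- function(x, ...) {
  tibble::tibble(attention = x$spec$attention, norm = x$spec$norm,
                 activation = x$spec$activation, af_node = x$spec$af_node,
                 layers_567 = paste(x$spec$layers_567, collapse = ","),
                 num_classes = x$spec$num_classes,
                 input_resolution = x$spec$input_resolution,
                 params = count_params(x),
                 macs = count_macs(x))
}

#' Tidy a training run
#'
#' @param x an `fcaenet_fit` from [train()].
#' @param ... unused.
#' @return the per-epoch history tibble.
#' @export
tidy.fcaenet_fit <- function(x, ...) x$history

#' @rdname tidy.fcaenet_fit
#' @export
glance.fcaenet_fit <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_valid_acc = x$best_valid_acc,
                 final_train_loss = utils::tail(x$history$train_loss, 1),
                 best_valid_loss = best$valid_loss)
}

#' Tidy a confusion matrix
#'
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @return long tibble with `truth`, `pred`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)))
  names(df) <- c("truth", "pred", "n")
  tibble::as_tibble(df)
}
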