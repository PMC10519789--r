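# ggplot2 visualizations.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_line
#'   geom_raster facet_wrap labs scale_fill_gradient scale_fill_viridis_c
#'   theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a confusion matrix
#'
#' @param object a `confusion_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy.confusion_matrix(object)
  ggplot(df, aes(x = .data$pred, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), size = 3) +
    scale_fill_gradient(low = "white", high = "#2c7fb8") +
    coord_equal() +
    labs(x = "predicted class", y = "true class", fill = "images") +
    theme_minimal()
}

#' Plot a training history
#'
#' Loss and accuracy per epoch for the training and validation sets.
#'
#' @param object an `fcaenet_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fcaenet_fit <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(c("train_loss", "valid_loss", "train_acc", "valid_acc"),
                        names_to = c("set", "metric"), names_sep = "_") |>
    dplyr::mutate(metric = ifelse(.data$metric == "acc", "accuracy", "loss"))
  ggplot(h, aes(x = .data$epoch, y = .data$value, colour = .data$set)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a Grad-CAM heatmap
#'
#' @param object a `cam_heatmap` from [grad_cam()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cam_heatmap <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- m[cbind(df$row, df$col)]
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "attention") +
    theme_minimal()
}

#' Plot the learning-rate schedule
#'
#' @param cfg a [train_config()].
#' @return a ggplot of learning rate against epoch.
#' @export
plot_lr_schedule <- function(cfg) {
  df <- tibble::tibble(epoch = seq_len(cfg$epochs) - 1L)
  df$lr <- lr_at(df$epoch, cfg)
  ggplot(df, aes(x = .data$epoch, y = .data$lr)) +
    geom_line() +
    labs(x = "epoch", y = "learning rate") +
    theme_minimal()
}
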