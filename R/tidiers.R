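## broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run into its per-epoch history
#'
#' @param x a `scmix_run`. @param ... unused.
#' @return tibble with columns epoch, train_loss, train_acc, val_loss,
#'   val_acc.
#' @export
tidy.scmix_run <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x a `scmix_run`. @param ... unused.
#' @return tibble with variant, epochs, best_epoch, best_val_acc, final
#'   losses, and parameter count.
#' @export
glance.scmix_run <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(variant = x$model_cfg$variant, epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_acc = x$best_val_acc,
                 final_train_loss = last$train_loss,
                 final_train_acc = last$train_acc,
                 n_params = count_parameters(x$model))
}

#' Tidy an evaluation into per-class metric rows
#'
#' @param x a `scmix_eval`. @param ... unused.
#' @return tibble of per-class rows (MACRO row excluded).
#' @export
tidy.scmix_eval <- function(x, ...) x$report[x$report$class != "MACRO", ]

#' One-row macro summary of an evaluation
#'
#' @param x a `scmix_eval`. @param ... unused.
#' @return tibble with macro acc/pr/re/f1 and pooled accuracy.
#' @export
glance.scmix_eval <- function(x, ...) {
  macro <- x$report[x$report$class == "MACRO", c("acc", "pr", "re", "f1")]
  dplyr::bind_cols(macro, tibble::tibble(pooled_acc = x$pooled_acc))
}

#' Tidy an ablation study into its comparison table
#'
#' @param x a `scmix_ablation`. @param ... unused.
#' @return tibble with one row per variant.
#' @export
tidy.scmix_ablation <- function(x, ...) x$table

#' Heatmap of a confusion matrix
#'
#' @param object a confusion matrix from [confusion_matrix()].
#' @param ... unused.
#' @return a ggplot object (true class on the y axis, predicted on the x).
#' @export
autoplot.scmix_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted label", y = "true label") +
    ggplot2::theme_minimal()
}

#' Training curves of a run
#'
#' @param object a `scmix_run`. @param ... unused.
#' @return a ggplot object with loss and accuracy panels over epochs.
#' @export
autoplot.scmix_run <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss, metric = "loss", split = "train"),
    tibble::tibble(epoch = h$epoch, value = h$val_loss, metric = "loss", split = "validation"),
    tibble::tibble(epoch = h$epoch, value = h$train_acc, metric = "accuracy", split = "train"),
    tibble::tibble(epoch = h$epoch, value = h$val_acc, metric = "accuracy", split = "validation"))
  ggplot2::ggplot(long[!is.na(long$value), ],
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
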