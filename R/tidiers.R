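# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted MIL model
#'
#' @param x a `mil_model`.
#' @param ... unused.
#' @return per-epoch tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.mil_model <- function(x, ...) x$history

#' One-row model summary
#'
#' @param x a `mil_model`.
#' @param ... unused.
#' @return tibble with loss kind, gene count, input dimension, epochs run,
#'   best epoch and best validation loss.
#' @export
glance.mil_model <- function(x, ...) {
  tibble::tibble(loss = x$loss_kind, level = x$level,
                 n_genes = length(x$gene_ids), input_dim = x$input_dim,
                 n_epochs = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_loss = x$best_val_loss, encoder = x$encoder_tag)
}

#' Training-curve plot
#'
#' @param object a `mil_model`.
#' @param ... unused.
#' @return a ggplot of train/validation loss per epoch with the selected
#'   (best-validation) epoch marked.
#' @export
autoplot.mil_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "epoch", y = paste0(object$loss_kind, " loss"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return the per-gene metric tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_gene

#' One-row metrics summary
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return wide tibble of metric means and bootstrap interval bounds.
#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "ci_low", "ci_high"))
  dplyr::bind_cols(tibble::tibble(level = x$level), wide)
}

#' Per-gene metric distribution plot
#'
#' @param object a `metrics_report`.
#' @param metric which per-gene metric to plot (default `"pcc"`).
#' @param ... unused.
#' @return a ggplot histogram of the per-gene metric with its mean marked.
#' @export
autoplot.metrics_report <- function(object, metric = "pcc", ...) {
  df <- object$per_gene[!is.na(object$per_gene[[metric]]), ]
  m <- object$summary$mean[object$summary$metric == metric]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = m, linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = sprintf("per-gene %s (%s level)", toupper(metric), object$level),
                  y = "genes") +
    ggplot2::theme_minimal()
}
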