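# ggplot2 displays for cross-validation results and training histories.

#' Plot per-fold cross-validation metrics
#'
#' @param object An `aop_cv` result from [cross_validate()].
#' @param metrics Metric columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aop_cv <- function(object,
                            metrics = c("accuracy", "precision", "sensitivity",
                                        "specificity", "mcc"), ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("fold", metrics)],
    cols = -"fold", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08),
                        size = 2) +
    ggplot2::labs(x = NULL, y = "value", colour = "fold",
                  title = "Cross-validated classification metrics") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training (and, when available, validation) loss per epoch, with the
#' best epoch marked.
#'
#' @param fit An `aop_fit`.
#' @return A ggplot object.
#' @export
plot_training_history <- function(fit) {
  stopifnot(inherits(fit, "aop_fit"))
  h <- fit$history
  long <- tidyr::pivot_longer(
    h[, c("epoch", "train_loss", "valid_loss")],
    cols = -"epoch", names_to = "series", values_to = "loss"
  )
  long <- long[!is.na(long$loss), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training history", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
  if (!all(is.na(h$valid_loss)) && fit$best_epoch > 0) {
    p <- p + ggplot2::geom_vline(xintercept = fit$best_epoch,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
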