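# ggplot2 autoplot methods for the three result types.

#' @describeIn confusion_matrix Heatmap of the confusion matrix (truth on
#'   the y axis, predictions on the x axis).
#' @param object The object to plot.
#' @export
autoplot.glu_confusion <- function(object, ...) {
  df <- tidy.glu_confusion(object)
  lv <- rownames(object)
  df$truth <- factor(df$truth, levels = rev(lv))
  df$estimate <- factor(df$estimate, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(
      x = "Predicted concentration (mg/dL)",
      y = "True concentration (mg/dL)", fill = "count"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn train_model Training and validation loss curves.
#' @param object The history to plot.
#' @export
autoplot.glucnn_history <- function(object, ...) {
  df <- tidy.glucnn_history(object)
  ggplot2::ggplot(
    df[!is.na(df$loss), ],
    ggplot2::aes(.data$epoch, .data$loss, colour = .data$curve)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(train_loss = "#2c7bb6", valid_loss = "#fdae61"),
      labels = c(train_loss = "training", valid_loss = "validation")
    ) +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn compliance_report Predicted-vs-reference scatter with the
#'   ISO band limits (dashed) and the identity line.
#' @param object The report to plot.
#' @export
autoplot.iso_report <- function(object, ...) {
  rng <- range(object$pairs$true)
  grid <- seq(max(rng[1] - 20, 1), rng[2] + 20, length.out = 200)
  upper <- ifelse(grid < object$threshold,
    grid + object$absolute_band, grid * (1 + object$relative_band)
  )
  lower <- ifelse(grid < object$threshold,
    grid - object$absolute_band, grid * (1 - object$relative_band)
  )
  band <- tibble(true = grid, upper = upper, lower = lower)
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$true, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_line(
      data = band, ggplot2::aes(y = .data$upper),
      linetype = "dashed", colour = "#2c7bb6"
    ) +
    ggplot2::geom_line(
      data = band, ggplot2::aes(y = .data$lower),
      linetype = "dashed", colour = "#2c7bb6"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$within),
      alpha = 0.7, position = ggplot2::position_jitter(2, 2, seed = 1)
    ) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1a9641", `FALSE` = "#d7191c")) +
    ggplot2::labs(
      x = "Reference glucose (mg/dL)", y = "Predicted glucose (mg/dL)",
      colour = "within band"
    ) +
    ggplot2::theme_minimal()
}
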