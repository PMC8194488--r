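#' Plot a confusion matrix as a heat map
#'
#' Rows are true classes, columns predicted classes, fills the row-normalized
#' percentages.
#'
#' @param object A `ser_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ser_eval
#' @export
autoplot.ser_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate,
    y = factor(.data$truth, levels = rev(sort(unique(.data$truth)))),
    fill = .data$percent
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 na.value = "grey90") +
    ggplot2::labs(x = "predicted", y = "true", fill = "% of row",
                  title = sprintf("UAR %.3f, ACC %.3f", object$uar,
                                  object$acc)) +
    ggplot2::theme_minimal()
}

#' Plot a group-by-emotion contingency table as grouped bars
#'
#' @param object A `ser_contingency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ser_contingency
#' @export
autoplot.ser_contingency <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emotion, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "emotion", y = "defendants", fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot the training loss curve
#'
#' @param object A trained `ser_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ser_model
#' @export
autoplot.ser_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
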