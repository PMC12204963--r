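# ggplot2 displays for training histories, predictions and metric reports.

#' @describeIn train_model Training-history curves (loss and validation
#'   accuracy by epoch).
#' @param object A `phase_model`.
#' @export
autoplot.phase_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot(h, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y", ncol = 1) +
    labs(x = "epoch", y = NULL,
         title = sprintf("%d-class model training", length(object$classes))) +
    theme_minimal()
}

#' Confusion-matrix tile plot
#'
#' @param predicted,truth Label vectors, or a prediction tibble given as
#'   `predicted` (then `truth` is taken from its `true_phase` column and the
#'   labels from `label_raw`).
#' @param classes Class set.
#' @return A ggplot object.
#' @export
plot_confusion <- function(predicted, truth = NULL, classes = PHASES4) {
  if (is.data.frame(predicted)) {
    truth <- predicted$true_phase
    predicted <- predicted$label_raw
  }
  cm <- as_tibble(as.data.frame(table(
    truth = factor(truth, classes), predicted = factor(predicted, classes))))
  ggplot(cm, aes(x = .data$predicted, y = .data$truth, fill = .data$Freq)) +
    geom_tile() +
    geom_text(aes(label = .data$Freq)) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted phase", y = "true phase") +
    theme_minimal()
}

#' @describeIn metrics_from_counts Per-class metric bars.
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    select(as_tibble(object), "class", "sensitivity", "specificity",
           "accuracy", "ppv", "npv"),
    -"class", names_to = "metric", values_to = "percent")
  ggplot(long, aes(x = .data$class, y = .data$percent)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    labs(x = NULL, y = "%") +
    theme_minimal()
}
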