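#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x An `ehrt_model`.
#' @param ... Unused.
#' @return Tibble of per-epoch records (`epoch`, `loss` and, for
#'   pretraining, `precision`).
#' @method tidy ehrt_model
#' @export
tidy.ehrt_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric())
}

#' One-row model summary
#'
#' @param x An `ehrt_model`.
#' @param ... Unused.
#' @return Tibble with the architecture, active channels, parameter count,
#'   stage and final training loss.
#' @method glance ehrt_model
#' @export
glance.ehrt_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers, n_heads = x$config$n_heads,
    hidden_size = x$config$hidden_size,
    intermediate_size = x$config$intermediate_size,
    channels = paste(sort(x$config$active_channels), collapse = "+"),
    n_parameters = param_count(x),
    stage = x$stage,
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report` from [evaluate_model()].
#' @param ... Unused.
#' @return The per-patient tibble (`patient_id`, `aps`, `auroc`,
#'   `n_positive`).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_patient

#' One-row evaluation summary
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `mean_aps`, `mean_auroc`, `n_patients`,
#'   `n_auroc_excluded`.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(mean_aps = x$mean_aps, mean_auroc = x$mean_auroc,
                 n_patients = x$n_patients,
                 n_auroc_excluded = x$n_auroc_excluded)
}

#' Plot a training history
#'
#' @param object An `ehrt_model` with a training history.
#' @param ... Unused.
#' @return A ggplot of loss (and MLM precision, if present) by epoch.
#' @method autoplot ehrt_model
#' @export
autoplot.ehrt_model <- function(object, ...) {
  hist <- tidy(object)
  long <- tidyr::pivot_longer(hist, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Plot per-patient metric distributions
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot of the per-patient APS and AUROC distributions.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_patient, c("aps", "auroc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~ .data$metric) +
    ggplot2::labs(x = NULL, y = "patients",
                  title = "Per-patient evaluation metrics")
}

#' Plot an attention association map
#'
#' @param object An [attention_map()].
#' @param ... Unused.
#' @return A ggplot heat map of aggregated last-layer attention.
#' @method autoplot attention_map
#' @export
autoplot.attention_map <- function(object, ...) {
  df <- expand.grid(query = seq_along(object$labels),
                    key = seq_along(object$labels))
  df$weight <- as.numeric(object$matrix[cbind(df$query, df$key)])
  df$query <- factor(object$labels[df$query], levels = rev(object$labels))
  df$key <- factor(object$labels[df$key], levels = object$labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$key, y = .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::labs(title = paste("Attention map,", object$patient_id),
                  x = "attended token", y = "query token") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
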