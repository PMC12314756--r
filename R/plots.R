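# ggplot2 displays for experiment tables and fitted detectors.

.PLOT_METRICS <- c("macro_F1", "G_mean", "recall_1", "precision_0", "FPR")

#' Plot an experiment table
#'
#' Metric-versus-condition display: line chart when the experiment key is
#' numeric (weight sweeps, stability curves), dodged bar chart otherwise
#' (model comparison, ablation).
#'
#' @param object A `tdt_experiment` tibble.
#' @param metrics Metric columns to show (default macro-F1, G-mean,
#'   recall_1, precision_0 and FPR).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tdt_experiment <- function(object, metrics = .PLOT_METRICS, ...) {
  name <- attr(object, "experiment") %||% "experiment"
  tbl <- tibble::as_tibble(object)
  key <- setdiff(
    names(tbl), c(.METRIC_COLS, "macro_F1_sd", "G_mean_sd", "n_seeds", "n_train")
  )[1]
  long <- tidyr::pivot_longer(
    tbl[c(key, metrics)], -dplyr::all_of(key),
    names_to = "metric", values_to = "value"
  )
  if (is.numeric(tbl[[key]])) {
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data[[key]], y = .data$value, colour = .data$metric
    )) +
      ggplot2::geom_line() +
      ggplot2::geom_point()
  } else {
    long[[key]] <- factor(long[[key]], unique(long[[key]]))
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data[[key]], y = .data$value, fill = .data$metric
    )) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  }
  p + ggplot2::labs(
    title = paste("Experiment:", name), y = "metric value (proportion)"
  )
}

#' Plot a detector training trace
#'
#' @param object A `tdt_gcn`.
#' @param ... Unused.
#' @return A ggplot object showing the training loss per epoch.
#' @export
autoplot.tdt_gcn <- function(object, ...) {
  df <- tibble::tibble(
    epoch = seq_along(object$loss_trace), loss = object$loss_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "cost-sensitive training loss")
}

#' Plot score distribution of a cohort
#'
#' Histogram of scale scores coloured by ideation group, with the
#' mean-plus-SD threshold marked.
#'
#' @param cohort A `tdt_cohort`.
#' @param binwidth Histogram bin width in points (default 2).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(cohort, binwidth = 2) {
  df <- tibble::tibble(
    score = cohort$scores,
    group = factor(cohort$labels, c(0, 1), c("low ideation", "high ideation"))
  )
  thr <- mean(cohort$scores) + stats::sd(cohort$scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "stack") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = "scale score (points)", y = "subjects")
}
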