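#' Plot a recording segment with detected beats
#'
#' Stacked channel traces over a time window, optionally overlaying detected
#' beat times.
#'
#' @param rec A [recording()].
#' @param from,to Window in seconds.
#' @param beat_times Optional numeric vector of beat times (s).
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, from = 0, to = min(10, duration_s(rec)),
                           beat_times = NULL) {
  idx <- which((seq_len(n_samples(rec)) - 1) / rec$fs >= from &
                 (seq_len(n_samples(rec)) - 1) / rec$fs <= to)
  dat <- rec$samples[idx, CHANNELS_IMU]
  dat$time <- (idx - 1) / rec$fs
  long <- tidyr::pivot_longer(dat, -"time", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = CHANNELS_IMU)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s (%s)", rec$subject_id,
                                  ifelse(is.na(rec$label), "unlabeled",
                                         rec$label)))
  if (!is.null(beat_times)) {
    bt <- beat_times[beat_times >= from & beat_times <= to]
    p <- p + ggplot2::geom_vline(xintercept = bt, colour = "red",
                                 linetype = "dashed", linewidth = 0.3)
  }
  p
}

#' @describeIn autoplot_cardiomech Shapley scores as a ranked bar chart.
#' @method autoplot cm_shapley
#' @export
autoplot.cm_shapley <- function(object, top_n = 20, ...) {
  dat <- tibble::tibble(feature = names(object$scores),
                        score = unname(object$scores)) |>
    dplyr::arrange(dplyr::desc(abs(.data$score))) |>
    head(top_n)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$feature,
                                                       abs(.data$score)),
                                    y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Shapley score",
                  title = sprintf("Shapley feature attribution (%s)",
                                  object$mode))
}

#' @describeIn autoplot_cardiomech Optimizer trace: probed (M, N) points
#'   coloured by objective value.
#' @method autoplot cm_filteropt
#' @export
autoplot.cm_filteropt <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$M, y = .data$N,
                                             colour = .data$f1)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("point", x = object$M_star, y = object$N_star,
                      shape = 4, size = 4, colour = "red") +
    ggplot2::labs(x = "RMS window M (ms)", y = "chunk length N (s)",
                  colour = "CV F1",
                  title = "Filter-parameter optimization trace")
}

#' @describeIn autoplot_cardiomech Row-normalized confusion matrix heat map.
#' @method autoplot cm_metrics
#' @export
autoplot.cm_metrics <- function(object, ...) {
  rates <- confusion_rates(object)
  dat <- tibble::as_tibble(as.data.frame(as.table(rates),
                                         responseName = "rate"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pred, y = .data$truth,
                                    fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%",
                                                    100 * .data$rate))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted", y = "true", fill = "row fraction",
                  title = "Confusion matrix (row-normalized)")
}

#' autoplot methods for cardiomech result objects
#'
#' @param object A result object (`cm_shapley`, `cm_filteropt`,
#'   `cm_metrics`).
#' @param top_n For Shapley results, number of features shown.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot_cardiomech
NULL
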