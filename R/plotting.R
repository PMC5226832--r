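# ggplot2 visualizations: sleep matrices, metric distributions, cohort
# densities, model-comparison ranks.

#' Plot a sleep matrix
#'
#' Days (rows, most recent at the bottom) by time bins (columns): blue
#' shading shows the posterior probability of sleep per bin, red dots the
#' event counts (dot area scales with the count), and an optional ground
#' truth as an outlined overlay.
#'
#' @param object A `sleep_estimate`.
#' @param truth Optional `ground_truth` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleep_estimate <- function(object, truth = NULL, ...) {
  ws <- object$counts$window_start_hour
  bm <- object$spec$bin_minutes
  df <- tibble::tibble(
    day = rep(object$counts$day_labels, times = ncol(object$prob)),
    bin = rep(seq_len(ncol(object$prob)) - 1L, each = nrow(object$prob)),
    p_sleep = as.numeric(object$prob),
    count = as.integer(object$counts$counts)
  )
  brk <- seq(0, object$spec$n, by = 4 * 60 / bm)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$day)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$p_sleep)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1), name = "P(sleep)") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$count > 0),
                        ggplot2::aes(size = .data$count),
                        colour = "red", alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 2, name = "events") +
    ggplot2::scale_x_continuous(breaks = brk,
                                labels = format_clock(bin_to_clock(brk, ws, bm)),
                                expand = c(0, 0)) +
    ggplot2::scale_y_date(expand = c(0, 0)) +
    ggplot2::labs(x = "local time", y = NULL,
                  title = paste("Sleep matrix:", object$counts$user_id)) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tr <- tibble::tibble(
      day = rep(truth$day_labels, times = ncol(truth$Z)),
      bin = rep(seq_len(ncol(truth$Z)) - 1L, each = nrow(truth$Z)),
      z = as.integer(truth$Z)
    )
    p <- p + ggplot2::geom_tile(data = dplyr::filter(tr, .data$z == 1L),
                                fill = NA, colour = "black",
                                linetype = "dotted", linewidth = 0.2)
  }
  p
}

#' Plot a fitted model's sleep matrix
#'
#' Convenience wrapper: [infer_sleep_matrix()] then
#' [autoplot.sleep_estimate()].
#'
#' @param object A `sleep_fit`.
#' @param ... Passed to [autoplot.sleep_estimate()].
#' @return A ggplot.
#' @export
autoplot.sleep_fit <- function(object, ...) {
  autoplot(infer_sleep_matrix(object), ...)
}

#' Plot cohort sleep/wake time densities
#'
#' Weighted densities of the pooled posterior sleep (blue) and wake (green)
#' clock times, faceted by weekday when the summary was grouped that way.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  ws <- object$window_start_hour
  bm <- object$bin_minutes
  df <- tidyr::pivot_longer(object$samples, c("t_sleep", "t_awake"),
                            names_to = "which", values_to = "bin")
  df$which <- ifelse(df$which == "t_sleep", "sleep time", "wake time")
  if (object$group_by == "weekday") {
    lv <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday")
    df$group <- factor(df$group, levels = lv)
  }
  brk <- seq(0, 24 * 60 / bm, by = 4 * 60 / bm)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, weight = .data$weight,
                                        fill = .data$which,
                                        colour = .data$which)) +
    ggplot2::geom_density(alpha = 0.3, bw = 1) +
    ggplot2::scale_fill_manual(values = c("sleep time" = "#2171b5",
                                          "wake time" = "#238b45"),
                               name = NULL) +
    ggplot2::scale_colour_manual(values = c("sleep time" = "#2171b5",
                                            "wake time" = "#238b45"),
                                 name = NULL) +
    ggplot2::scale_x_continuous(breaks = brk,
                                labels = format_clock(bin_to_clock(brk, ws, bm))) +
    ggplot2::labs(x = "local time", y = "density") +
    ggplot2::theme_minimal()
  if (object$group_by == "weekday") {
    p <- p + ggplot2::facet_wrap(~group, ncol = 1)
  }
  p
}

#' Plot per-user metric distributions
#'
#' Histograms (default) or complementary cumulative distributions of the
#' per-user accuracy, precision, recall, and F1 scores, optionally split by
#' method (Bayesian vs rule baseline).
#'
#' @param metrics Tibble from [score_sleep()] rows (needs `accuracy`,
#'   `precision`, `recall`, `f1`; an optional `method` column splits lines).
#' @param type `"histogram"` or `"ccdf"`.
#' @return A ggplot.
#' @export
plot_metric_distribution <- function(metrics, type = c("histogram", "ccdf")) {
  type <- match.arg(type)
  if (!"method" %in% names(metrics)) metrics$method <- "bayes"
  df <- tidyr::pivot_longer(metrics,
                            c("accuracy", "precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  if (type == "histogram") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$method)) +
      ggplot2::geom_histogram(breaks = seq(0, 1, by = 0.05),
                              position = "identity", alpha = 0.6) +
      ggplot2::facet_wrap(~metric) +
      ggplot2::labs(x = "score", y = "users") +
      ggplot2::theme_minimal()
  } else {
    df <- df |>
      dplyr::group_by(.data$method, .data$metric) |>
      dplyr::arrange(.data$value, .by_group = TRUE) |>
      dplyr::mutate(ccdf = 1 - (dplyr::row_number() - 1) / dplyr::n()) |>
      dplyr::ungroup()
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$ccdf,
                                     colour = .data$method)) +
      ggplot2::geom_step() +
      ggplot2::facet_wrap(~metric) +
      ggplot2::labs(x = "score", y = "P(score ≥ x)") +
      ggplot2::theme_minimal()
  }
}

#' Plot relative DIC by variant
#'
#' @param object A `model_comparison`.
#' @param ... Unused.
#' @return A ggplot of per-user relative DIC (vs pooled-pooled), ordered by
#'   cohort mean.
#' @export
autoplot.model_comparison <- function(object, ...) {
  ord <- object$cohort$variant[order(object$cohort$mean_rel_dic,
                                     decreasing = TRUE)]
  df <- object$per_user
  df$variant <- factor(df$variant, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$rel_dic)) +
    ggplot2::geom_boxplot(fill = "#9ecae1") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "relative DIC (vs pooled-pooled)") +
    ggplot2::theme_minimal()
}
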