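#' Plot a segmented TUG trial
#'
#' Rectified pitch and yaw angular velocity with the six detected sub-task
#' intervals shaded and the detection thresholds drawn.
#'
#' @param rec the TUG [imu_recording()].
#' @param seg its `tug_segmentation` (computed if `NULL`).
#' @param spec the [threshold_spec()] used.
#' @return A ggplot object.
#' @export
plot_tug_segmentation <- function(rec, seg = NULL, spec = threshold_spec()) {
  if (is.null(seg)) seg <- segment_tug(rec, spec)
  df <- tibble(time_s = rep(rec$time_s, 2),
               value = c(rectify(rec$pitch), rectify(rec$yaw)),
               channel = rep(c("pitch", "yaw"), each = nrow(rec)))
  thr <- tibble(channel = c("pitch", "yaw"),
                threshold = c(spec$pitch_thresh, spec$yaw_thresh))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_rect(
      data = as_tibble(seg), inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$subtask),
      alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "angular velocity (deg/s)",
                  fill = "sub-task")
}

#' Predicted versus true age for a fitted model
#'
#' @param object a `gaitage_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gaitage_fit <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "true age (years)", y = "predicted age (years)",
      title = sprintf("%s model: MAE %.2f y, MAPE %.2f%%",
                      object$feature_set, object$mae, object$mape))
}

#' Top feature importances of a fitted model
#'
#' @param fit a `gaitage_fit`.
#' @param top_n how many features to show.
#' @return A ggplot object.
#' @export
plot_feature_importance <- function(fit, top_n = 5) {
  df <- head(tidy(fit), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$feature, .data$score))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "feature importance score", y = NULL,
                  title = paste0(fit$feature_set, " model"))
}

#' MAE/MAPE comparison across feature sets
#'
#' @param object a `gaitage_comparison`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gaitage_comparison <- function(object, ...) {
  df <- object$summary %>%
    tidyr::pivot_longer(c("mae", "mape"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_set, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "feature set", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
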