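#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics report
#'
#' @param x a `leak_metrics`.
#' @param ... unused.
#' @return one-row tibble with the window/frame accuracies, FAR, FRR,
#'   precision, recall and F1 (all percent).
#' @export
tidy.leak_metrics <- function(x, ...) {
  tibble::tibble(accuracy_windows = x$accuracy_windows,
                 accuracy_frames = x$accuracy_frames,
                 far = x$far, frr = x$frr, precision = x$precision,
                 recall = x$recall, f1 = x$f1)
}

#' @rdname tidy.leak_metrics
#' @export
glance.leak_metrics <- function(x, ...) tidy.leak_metrics(x, ...)

#' Tidy a Welch test result
#'
#' @param x a `welch_result`.
#' @param ... unused.
#' @return one-row tibble: estimate (mean difference), statistic, df,
#'   p.value, conf.low, conf.high.
#' @export
tidy.welch_result <- function(x, ...) {
  tibble::tibble(estimate = x$mean_difference, statistic = x$t_statistic,
                 df = x$degrees_of_freedom, p.value = x$p_value,
                 conf.low = x$ci95_low, conf.high = x$ci95_high)
}

#' Tidy an experiment report
#'
#' @param x a `leak_experiment`.
#' @param ... unused.
#' @return the per-run metric tibble.
#' @export
tidy.leak_experiment <- function(x, ...) x$report

#' @rdname tidy.leak_experiment
#' @export
glance.leak_experiment <- function(x, ...) {
  x$report |>
    dplyr::group_by(.data$task, .data$amount) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c("accuracy_windows", "accuracy_frames", "far", "frr",
        "precision", "recall", "f1")), mean), .groups = "drop")
}

#' Plot a scalogram image
#'
#' @param object a `scalogram`.
#' @param ... unused.
#' @return a ggplot: time against log-spaced frequency, fill = normalized
#'   CWT magnitude.
#' @export
autoplot.scalogram <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_along(object$freq_axis),
                           col = seq_along(object$time_axis))
  df$value <- object$pixels[cbind(df$row, df$col)]
  df$time <- object$time_axis[df$col]
  df$freq <- object$freq_axis[df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "magnitude")
}

#' Plot temporal-aggregation curves
#'
#' @param object an `aggregation_curve`.
#' @param which `"per_subject"` (accuracy vs duration per subject) or
#'   `"cohort"` (cumulative fraction of subjects at >= 95% accuracy).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aggregation_curve <- function(object,
                                       which = c("per_subject", "cohort"),
                                       ...) {
  which <- match.arg(which)
  if (which == "per_subject") {
    ggplot2::ggplot(object$per_subject,
                    ggplot2::aes(x = .data$duration_bin, y = .data$accuracy,
                                 colour = .data$subject_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "aggregated duration (s)", y = "mean run accuracy",
                    colour = "subject")
  } else {
    ggplot2::ggplot(object$cohort,
                    ggplot2::aes(x = .data$duration_bin,
                                 y = .data$fraction_confident)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "aggregated duration (s)",
                    y = "fraction of subjects at ≥ 95% accuracy")
  }
}

#' Plot Grad-CAM class heatmaps
#'
#' @param object a `grad_cam_map`.
#' @param ... unused.
#' @return a ggplot faceted by class.
#' @export
autoplot.grad_cam_map <- function(object, ...) {
  dfs <- purrr::imap(object$maps, function(m, key) {
    if (is.null(m)) return(NULL)
    df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
    df$value <- m[cbind(df$row, df$col)]
    df$class <- paste("class", key)
    df
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (px)", y = "frequency (px)", fill = "attention")
}
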