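# ggplot2 autoplot methods for result objects.

#' Plot a detector ROC
#'
#' False positives per second against sensitivity, one point per
#' threshold, with an optional highlighted operating point.
#'
#' @param object A `gw_roc` table from [build_roc()].
#' @param operating_point Optional threshold to highlight (e.g. the value
#'   returned by [select_operating_point()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gw_roc <- function(object, operating_point = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$fp_per_s,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "false positives per second", y = "sensitivity",
                  title = "Face-detector ROC") +
    ggplot2::theme_minimal()
  if (!is.null(operating_point)) {
    row <- object[which.min(abs(object$threshold - operating_point)), ]
    p <- p + ggplot2::geom_point(data = row, colour = "red", size = 3,
                                 shape = 1, stroke = 1.2)
  }
  p
}

#' Plot fitted angular limits
#'
#' One panel per grid cell showing the fitted yaw/pitch window as a
#' rectangle, so the region-conditional calibration can be inspected at a
#' glance.
#'
#' @param object A `gw_limits` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gw_limits <- function(object, ...) {
  td <- tidy(object)
  td$panel <- sprintf("cell %d (r%d,c%d), n=%d",
                      td$cell, td$row, td$col, td$n)
  ggplot2::ggplot(td) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$yaw_lo,
                                    xmax = .data$yaw_hi,
                                    ymin = .data$pitch_lo,
                                    ymax = .data$pitch_hi),
                       fill = "steelblue", alpha = 0.4, colour = "grey30") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "yaw (degrees)", y = "pitch (degrees)",
                  title = sprintf("Gaze-on-screen windows (tv %s)",
                                  attr(object, "tv_position"))) +
    ggplot2::theme_minimal()
}

#' Plot a viewing log timeline
#'
#' Viewing status over session time; pass a gold log to overlay the
#' coder's watching indicator for visual comparison.
#'
#' @param object A `gw_viewing_log`.
#' @param gold Optional gold-log tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gw_viewing_log <- function(object, gold = NULL, ...) {
  fps <- attr(object, "fps")
  df <- tibble::tibble(t = object$frame_index / fps,
                       viewing = object$viewing, series = "estimate")
  if (!is.null(gold)) {
    codes <- expand_gold(gold, nrow(object))
    df <- dplyr::bind_rows(df, tibble::tibble(
      t = object$frame_index / fps,
      viewing = codes == "watching", series = "gold"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$series,
                                   fill = .data$viewing)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "darkgreen",
                                          `FALSE` = "grey85")) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "viewing",
                  title = "Television viewing timeline") +
    ggplot2::theme_minimal()
}
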