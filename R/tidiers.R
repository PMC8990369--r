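# broom-style tidiers for the package's result objects.

#' Tidy an agreement report
#'
#' @param x A `gw_agreement` object.
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value` (one row per
#'   statistic).
#' @export
tidy.gw_agreement <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    metric = c("tp", "tn", "fp", "fn",
               "accuracy", "sensitivity", "specificity", "ppv", "npv", "fpr",
               "pabak", "pabak_ci_low", "pabak_ci_high", "kappa",
               "icc_frame"),
    value = c(x$counts[["tp"]], x$counts[["tn"]], x$counts[["fp"]],
              x$counts[["fn"]],
              m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv, m$fpr,
              x$pabak, unname(x$pabak_ci["low"]), unname(x$pabak_ci["high"]),
              x$kappa, x$icc_frame))
}

#' Glance at an agreement report
#'
#' @param x A `gw_agreement` object.
#' @param ... Unused.
#' @return A one-row tibble of the headline statistics.
#' @export
glance.gw_agreement <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble::tibble(pabak = x$pabak, kappa = x$kappa,
                   icc_frame = x$icc_frame, icc_band = x$icc_band,
                   n_used = x$n_used, n_dropped = x$n_dropped))
}

#' Tidy an angular-limit map
#'
#' @param x A `gw_limits` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted cell, including the cell's
#'   grid row/column and window half-widths.
#' @export
tidy.gw_limits <- function(x, ...) {
  g <- attr(x, "grid")
  tibble::tibble(
    cell = x$cell,
    row = x$cell %/% g[2], col = x$cell %% g[2],
    yaw_lo = x$yaw_lo, yaw_hi = x$yaw_hi,
    pitch_lo = x$pitch_lo, pitch_hi = x$pitch_hi,
    yaw_halfwidth = (x$yaw_hi - x$yaw_lo) / 2,
    pitch_halfwidth = (x$pitch_hi - x$pitch_lo) / 2,
    n = x$n)
}

#' Glance at an angular-limit map
#'
#' @param x A `gw_limits` object.
#' @param ... Unused.
#' @return One-row tibble: television position, grid shape, coverage
#'   quantile, fitted-cell count and total training frames.
#' @export
glance.gw_limits <- function(x, ...) {
  g <- attr(x, "grid")
  tibble::tibble(tv_position = attr(x, "tv_position"),
                 grid_rows = g[1], grid_cols = g[2],
                 coverage_quantile = attr(x, "coverage_quantile"),
                 yaw_only = isTRUE(attr(x, "yaw_only")),
                 n_cells_fitted = nrow(x), n_frames = sum(x$n))
}

#' Glance at a viewing log
#'
#' @param x A `gw_viewing_log`.
#' @param ... Unused.
#' @return One-row tibble: frame count, fps, viewing frames, total
#'   viewing seconds and the "m:ss" format.
#' @export
glance.gw_viewing_log <- function(x, ...) {
  tv <- total_viewing_time(x)
  tibble::tibble(n_frames = nrow(x), fps = attr(x, "fps"),
                 n_viewing = sum(x$viewing),
                 total_viewing_s = tv$seconds,
                 total_viewing = tv$formatted)
}
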