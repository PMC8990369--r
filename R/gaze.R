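# Gaze dichotomization: converting the verified target child's gaze
# direction vector into a binary gaze-on-screen decision through
# region-conditional angular limits, calibrated per television position and
# evaluated leave-one-family-out.

#' Yaw/pitch angles of a gaze vector
#'
#' Converts unit gaze vectors to angles in degrees:
#' `yaw = atan2(x, z)`, `pitch = atan2(-y, sqrt(x^2 + z^2))`, in the
#' camera-facing frame (x right, y down, z from the scene toward the
#' camera), so a gaze straight at the camera is (0, 0). The inverse is
#' [angles_to_gaze()].
#'
#' @param gaze Numeric matrix with columns (x, y, z), or a length-3 vector;
#'   rows must be unit-norm to 1e-6.
#' @return A tibble with columns `yaw`, `pitch` in degrees.
#' @export
#' @examples
#' gaze_angles(c(0, 0, 1))   # 0, 0
#' gaze_angles(c(1, 0, 0))   # 90, 0
gaze_angles <- function(gaze) {
  if (is.null(dim(gaze))) gaze <- matrix(gaze, ncol = 3)
  gaze <- as.matrix(gaze)
  nrm <- sqrt(rowSums(gaze^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    abort("gaze vectors must be unit-norm (tolerance 1e-6)",
          class = "gazewatch_gaze_error")
  }
  tibble::tibble(
    yaw = atan2(gaze[, 1], gaze[, 3]) * 180 / pi,
    pitch = atan2(-gaze[, 2], sqrt(gaze[, 1]^2 + gaze[, 3]^2)) * 180 / pi
  )
}

#' Gaze vector from yaw/pitch angles
#'
#' Inverse of [gaze_angles()]: reconstructs the unit vector
#' `(sin(yaw) cos(pitch), -sin(pitch), cos(yaw) cos(pitch))`.
#'
#' @param yaw,pitch Angles in degrees (vectorised).
#' @return Matrix with columns x, y, z; unit rows.
#' @export
angles_to_gaze <- function(yaw, pitch) {
  y <- yaw * pi / 180; p <- pitch * pi / 180
  cbind(x = sin(y) * cos(p), y = -sin(p), z = cos(y) * cos(p))
}

#' Grid cell of a face position
#'
#' Row-major 0-based index of the equal-sized grid cell containing a frame
#' position; points on the right or bottom frame edge belong to the last
#' cell of their row/column.
#'
#' @param cx,cy Position in pixels (vectorised); must lie inside the frame.
#' @param frame_size `c(width, height)` in pixels.
#' @param grid `c(rows, cols)`.
#' @return Integer cell indices in `0:(rows*cols - 1)`.
#' @export
#' @examples
#' region_of(320, 240, c(640, 480), c(3, 3))  # centre cell: 4
region_of <- function(cx, cy, frame_size, grid = c(3L, 3L)) {
  if (any(cx < 0 | cx > frame_size[1] | cy < 0 | cy > frame_size[2])) {
    abort("position outside the frame", class = "gazewatch_gaze_error")
  }
  col <- pmin(grid[2] - 1L, floor(cx / frame_size[1] * grid[2]))
  row <- pmin(grid[1] - 1L, floor(cy / frame_size[2] * grid[1]))
  as.integer(row * grid[2] + col)
}

#' Fit region-conditional angular limits for gaze-on-screen
#'
#' For one television position, pools all frames gold-coded `watching`
#' across the supplied training sessions, computes the observed gaze
#' yaw/pitch of the target child's face in each, and fits per-grid-cell
#' angular windows as the central `coverage_quantile` interval (default the
#' 5th--95th percentile) of those angles. Cells with fewer than
#' `min_samples` watching frames inherit the global windows pooled over all
#' cells.
#'
#' Only target faces (by simulator ground truth, or the faces you pass in)
#' contribute; pass `yaw_only = TRUE` to constrain yaw alone and leave
#' pitch unconstrained.
#'
#' @param sessions A `gw_session` or list of them (same `tv_position`).
#' @param grid `c(rows, cols)` partition of the frame (default 3x3).
#' @param coverage_quantile Central coverage of the fitted windows in
#'   (0, 1\]; default 0.9.
#' @param min_samples Minimum watching-frames per cell before the global
#'   fallback window is used instead (default 30).
#' @param yaw_only If `TRUE`, pitch windows are set to \[-90, 90\]
#'   (1-D yaw-only dichotomization).
#' @return An object of class `"gw_limits"`: a tibble with one row per
#'   fitted cell (`cell`, `yaw_lo`, `yaw_hi`, `pitch_lo`, `pitch_hi`, `n`)
#'   and attributes `grid`, `frame_size`, `tv_position`, `fallback`
#'   (global windows), `coverage_quantile`.
#' @export
fit_angular_limits <- function(sessions, grid = c(3L, 3L),
                               coverage_quantile = 0.9, min_samples = 30L,
                               yaw_only = FALSE) {
  if (inherits(sessions, "gw_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1,
            coverage_quantile > 0, coverage_quantile <= 1)
  tvp <- sessions[[1]]$config$tv_position
  fsz <- sessions[[1]]$config$frame_size
  obs <- purrr::map_dfr(sessions, function(s) {
    if (!identical(s$config$tv_position, tvp)) {
      abort("all training sessions must share one tv_position",
            class = "gazewatch_gaze_error")
    }
    codes <- expand_gold(s$gold, s$n_frames)
    f <- s$faces
    f <- f[f$true_identity == "target" &
             codes[f$frame_index + 1L] == "watching", , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    ang <- gaze_angles(cbind(f$gx, f$gy, f$gz))
    tibble::tibble(cell = region_of(f$x + f$w / 2, f$y + f$h / 2, fsz, grid),
                   yaw = ang$yaw, pitch = ang$pitch)
  })
  if (is.null(obs) || nrow(obs) == 0) {
    abort("no frames gold-coded watching: cannot fit angular limits",
          class = "gazewatch_gaze_error")
  }
  lo_q <- (1 - coverage_quantile) / 2
  hi_q <- 1 - lo_q
  win <- function(v) unname(quantile(v, c(lo_q, hi_q), type = 7))
  fallback <- c(win(obs$yaw), win(obs$pitch))
  names(fallback) <- c("yaw_lo", "yaw_hi", "pitch_lo", "pitch_hi")

  cells <- obs %>%
    dplyr::group_by(.data$cell) %>%
    dplyr::summarise(
      yaw_lo = quantile(.data$yaw, lo_q, type = 7, names = FALSE),
      yaw_hi = quantile(.data$yaw, hi_q, type = 7, names = FALSE),
      pitch_lo = quantile(.data$pitch, lo_q, type = 7, names = FALSE),
      pitch_hi = quantile(.data$pitch, hi_q, type = 7, names = FALSE),
      n = dplyr::n(), .groups = "drop")
  low <- cells$n < min_samples
  cells$yaw_lo[low] <- fallback["yaw_lo"]; cells$yaw_hi[low] <- fallback["yaw_hi"]
  cells$pitch_lo[low] <- fallback["pitch_lo"]; cells$pitch_hi[low] <- fallback["pitch_hi"]
  if (yaw_only) {
    cells$pitch_lo <- -90; cells$pitch_hi <- 90
    fallback["pitch_lo"] <- -90; fallback["pitch_hi"] <- 90
  }
  structure(cells,
            class = c("gw_limits", class(cells)),
            grid = as.integer(grid), frame_size = fsz, tv_position = tvp,
            fallback = fallback, coverage_quantile = coverage_quantile,
            yaw_only = yaw_only)
}

#' @export
print.gw_limits <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<gw_limits> tv: %s, grid %dx%d, coverage %.2f\n",
              attr(x, "tv_position"), g[1], g[2],
              attr(x, "coverage_quantile")))
  NextMethod()
}

# look up the per-cell window rows (falling back globally) for cell ids
limits_for_cells <- function(limits, cell) {
  fb <- attr(limits, "fallback")
  m <- match(cell, limits$cell)
  out <- cbind(
    yaw_lo = ifelse(is.na(m), fb["yaw_lo"], limits$yaw_lo[m]),
    yaw_hi = ifelse(is.na(m), fb["yaw_hi"], limits$yaw_hi[m]),
    pitch_lo = ifelse(is.na(m), fb["pitch_lo"], limits$pitch_lo[m]),
    pitch_hi = ifelse(is.na(m), fb["pitch_hi"], limits$pitch_hi[m])
  )
  rownames(out) <- NULL
  out
}

#' Dichotomize gaze: on-screen or not
#'
#' `TRUE` iff both the yaw and the pitch of the gaze vector lie within the
#' angular window of the grid cell containing the face (boundaries
#' inclusive). Gaze vectors are normalised before the angle computation,
#' so the decision is invariant to positive scaling.
#'
#' @param gaze Matrix (x, y, z) of gaze vectors (or length-3 vector).
#' @param cx,cy Face-box centre positions, pixels.
#' @param limits A [fit_angular_limits()] object.
#' @param tv_position Optional check: errors if it does not match the
#'   position the limits were fitted for.
#' @return Logical vector.
#' @export
classify_gaze <- function(gaze, cx, cy, limits, tv_position = NULL) {
  if (!inherits(limits, "gw_limits")) {
    abort("`limits` must be a gw_limits object", class = "gazewatch_gaze_error")
  }
  if (!is.null(tv_position) &&
      !identical(tv_position, attr(limits, "tv_position"))) {
    abort(sprintf("no angular limits fitted for tv_position \"%s\"",
                  tv_position), class = "gazewatch_gaze_error")
  }
  if (is.null(dim(gaze))) gaze <- matrix(gaze, ncol = 3)
  gaze <- as.matrix(gaze)
  nrm <- sqrt(rowSums(gaze^2))
  if (any(nrm <= 0)) {
    abort("zero gaze vector", class = "gazewatch_gaze_error")
  }
  ang <- gaze_angles(gaze / nrm)
  cell <- region_of(cx, cy, attr(limits, "frame_size"), attr(limits, "grid"))
  w <- limits_for_cells(limits, cell)
  ang$yaw >= w[, "yaw_lo"] & ang$yaw <= w[, "yaw_hi"] &
    ang$pitch >= w[, "pitch_lo"] & ang$pitch <= w[, "pitch_hi"]
}

#' Shrink or widen fitted angular windows
#'
#' Scales every window (including the global fallback) about its centre by
#' `factor`; useful for sensitivity analyses (a factor below 1 strictly
#' narrows every window, so the decisions it admits are a subset).
#'
#' @param limits A `gw_limits` object.
#' @param factor Positive scale factor.
#' @return A `gw_limits` object.
#' @export
scale_limits <- function(limits, factor) {
  stopifnot(factor > 0)
  sc <- function(lo, hi) {
    c0 <- (lo + hi) / 2; h <- (hi - lo) / 2 * factor
    list(lo = c0 - h, hi = c0 + h)
  }
  y <- sc(limits$yaw_lo, limits$yaw_hi)
  p <- sc(limits$pitch_lo, limits$pitch_hi)
  limits$yaw_lo <- y$lo; limits$yaw_hi <- y$hi
  limits$pitch_lo <- p$lo; limits$pitch_hi <- p$hi
  fb <- attr(limits, "fallback")
  yf <- sc(fb["yaw_lo"], fb["yaw_hi"]); pf <- sc(fb["pitch_lo"], fb["pitch_hi"])
  attr(limits, "fallback") <- c(yaw_lo = unname(yf$lo), yaw_hi = unname(yf$hi),
                                pitch_lo = unname(pf$lo), pitch_hi = unname(pf$hi))
  limits
}

#' Leave-one-family-out gaze evaluation
#'
#' For each television position with at least two families, holds out one
#' family at a time, fits angular limits on the remaining families'
#' sessions, classifies the held-out family's target faces on frames
#' gold-coded `watching` or `not_watching`, and reports confusion-matrix
#' metrics (plus FPR) per family. Positions with a single family are
#' skipped with a warning (such unique positions cannot be cross-fitted).
#'
#' @param sessions Named list of `gw_session` objects; names are family
#'   ids.
#' @param grid,coverage_quantile,min_samples Passed to
#'   [fit_angular_limits()].
#' @return A tibble with one row per evaluated family: `family`,
#'   `tv_position`, confusion counts, Table-2-style metrics and `fpr`.
#'   Summarise across families with [summarise_by_position()].
#' @export
loo_evaluate <- function(sessions, grid = c(3L, 3L),
                         coverage_quantile = 0.9, min_samples = 30L) {
  stopifnot(is.list(sessions), length(sessions) >= 2)
  if (is.null(names(sessions))) {
    names(sessions) <- sprintf("family%02d", seq_along(sessions))
  }
  tvp <- vapply(sessions, function(s) s$config$tv_position, character(1))
  rows <- list()
  for (pos in unique(tvp)) {
    fams <- names(sessions)[tvp == pos]
    if (length(fams) < 2) {
      warn(sprintf(
        "tv_position \"%s\" has a single family (%s): skipped from leave-one-out",
        pos, fams))
      next
    }
    for (fam in fams) {
      train <- sessions[setdiff(fams, fam)]
      lim <- fit_angular_limits(train, grid = grid,
                                coverage_quantile = coverage_quantile,
                                min_samples = min_samples)
      s <- sessions[[fam]]
      codes <- expand_gold(s$gold, s$n_frames)
      f <- s$faces
      f <- f[f$true_identity == "target" &
               codes[f$frame_index + 1L] %in% c("watching", "not_watching"), ]
      pred <- classify_gaze(cbind(f$gx, f$gy, f$gz),
                            f$x + f$w / 2, f$y + f$h / 2, lim)
      truth <- codes[f$frame_index + 1L] == "watching"
      cc <- confusion_counts(pred, truth)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(family = fam, tv_position = pos),
        tibble::as_tibble(as.list(cc)), metrics_from_counts(cc))
    }
  }
  if (length(rows) == 0) {
    abort("no tv_position had two or more families",
          class = "gazewatch_gaze_error")
  }
  dplyr::bind_rows(rows)
}

#' Summarise per-family metrics by television position
#'
#' Mean and range across families of each metric, mirroring how
#' per-position gaze results are reported; the family mean (not the pooled
#' frame count) is the default aggregation.
#'
#' @param per_family Output of [loo_evaluate()] (or any tibble with
#'   `tv_position` and metric columns).
#' @param metrics Character vector of metric columns to summarise.
#' @return Tibble with `tv_position`, `n_families` and, per metric, mean /
#'   min / max across families.
#' @export
summarise_by_position <- function(per_family,
                                  metrics = c("accuracy", "sensitivity",
                                              "specificity", "ppv", "npv",
                                              "fpr")) {
  per_family %>%
    dplyr::group_by(.data$tv_position) %>%
    dplyr::summarise(
      n_families = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         min = ~suppressWarnings(min(.x, na.rm = TRUE)),
                         max = ~suppressWarnings(max(.x, na.rm = TRUE)))),
      .groups = "drop")
}
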