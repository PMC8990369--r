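# Sequential composition of the three stages into a per-frame viewing log
# and a total viewing-time estimate.

new_viewing_log <- function(frame_index, viewing, fps) {
  x <- tibble::tibble(frame_index = as.integer(frame_index),
                      viewing = as.logical(viewing))
  structure(x, class = c("gw_viewing_log", class(x)), fps = fps)
}

#' Viewing log from a per-frame decision vector
#'
#' @param viewing Logical vector, one decision per frame (frame 0 first).
#' @param fps Frames per second.
#' @return A `gw_viewing_log` tibble (`frame_index`, `viewing`) with an
#'   `fps` attribute.
#' @export
viewing_log <- function(viewing, fps) {
  new_viewing_log(seq_along(viewing) - 1L, viewing, fps)
}

#' @export
print.gw_viewing_log <- function(x, ...) {
  tv <- total_viewing_time(x)
  cat(sprintf("<viewing log> %d frames at %g fps; viewing %s (%.1f s)\n",
              nrow(x), attr(x, "fps"), tv$formatted, tv$seconds))
  invisible(x)
}

#' Run the three-stage measurement pipeline
#'
#' Composes, per frame: detection-score thresholding
#' ([apply_threshold()]), target verification with track-based smoothing
#' ([verify_session()]), and gaze dichotomization of the verified target
#' ([classify_gaze()]). Frames with no verified target contribute
#' "no gaze" -- not identifying the target when there is no gaze does not
#' affect the final viewing time, and a frame without the child cannot be
#' a viewing frame.
#'
#' @param session A `gw_session` (or a list with `faces`, `n_frames`,
#'   `fps`, `config`).
#' @param gallery Enrollment gallery matrix ([enroll_gallery()]).
#' @param limits Fitted angular limits ([fit_angular_limits()]) for the
#'   session's television position.
#' @param tau_d Detection score threshold (default 0.5).
#' @param tau_v Verification match-score threshold (default 0.93).
#' @param window_frames Odd identity-smoothing window (default 15).
#' @param iou_assoc Track association IoU (default 0.3).
#' @return A `gw_viewing_log` covering every frame of the session, with
#'   attribute `"verified"` carrying the verified face tibble for
#'   inspection.
#' @export
#' @examples
#' \donttest{
#' s <- simulate_session(session_config(duration_s = 60, seed = 3))
#' g <- enroll_gallery(s, 5)
#' lim <- fit_angular_limits(s)
#' log <- run_pipeline(s, g, lim)
#' total_viewing_time(log)
#' }
run_pipeline <- function(session, gallery, limits,
                         tau_d = 0.5, tau_v = 0.93,
                         window_frames = 15L, iou_assoc = 0.3) {
  faces <- tryCatch(apply_threshold(session$faces, tau_d),
                    error = function(e) abort(
                      paste0("detection stage: ", conditionMessage(e)),
                      class = "gazewatch_pipeline_error"))
  ver <- tryCatch(verify_session(faces, gallery, tau_v = tau_v,
                                 window_frames = window_frames,
                                 iou_assoc = iou_assoc),
                  error = function(e) abort(
                    paste0("verification stage: ", conditionMessage(e)),
                    class = "gazewatch_pipeline_error"))
  tgt <- ver[ver$is_target, , drop = FALSE]
  on_tv <- tryCatch(
    if (nrow(tgt) > 0) {
      classify_gaze(cbind(tgt$gx, tgt$gy, tgt$gz),
                    tgt$x + tgt$w / 2, tgt$y + tgt$h / 2, limits,
                    tv_position = session$config$tv_position)
    } else logical(0),
    error = function(e) abort(paste0("gaze stage: ", conditionMessage(e)),
                              class = "gazewatch_pipeline_error"))
  viewing <- rep(FALSE, session$n_frames)
  viewing[tgt$frame_index[on_tv] + 1L] <- TRUE
  out <- new_viewing_log(seq_len(session$n_frames) - 1L, viewing, session$fps)
  attr(out, "verified") <- ver
  out
}

#' Total viewing time of a log
#'
#' The estimate is the count of viewing frames divided by the frame rate,
#' formatted "minutes:seconds" with zero-padded seconds.
#'
#' @param log A `gw_viewing_log`.
#' @return List with `seconds`, `minutes` and `formatted` ("m:ss").
#' @export
#' @examples
#' total_viewing_time(viewing_log(rep(TRUE, 450), 15))  # 30 s, "0:30"
total_viewing_time <- function(log) {
  fps <- attr(log, "fps")
  stopifnot(!is.null(fps))
  secs <- sum(log$viewing) / fps
  list(seconds = secs, minutes = secs / 60,
       formatted = format_mmss(secs))
}

format_mmss <- function(secs) {
  s <- round(secs)
  sprintf("%d:%02d", s %/% 60, s %% 60)
}

#' Smooth a viewing log into longer time epochs
#'
#' Relabels viewing over fixed epochs (for example 5, 15 or 30 s): an
#' epoch is a viewing epoch iff at least half of its frames are viewing
#' frames (ties count as viewing). The final, possibly partial, epoch is
#' judged by the same majority rule and contributes its actual duration.
#'
#' @param log A `gw_viewing_log`.
#' @param epoch_s Epoch length in seconds; `epoch_s * fps` must be >= 1.
#' @return A tibble of class `"gw_epoch_log"`: `epoch`, `start_frame`,
#'   `n_frames`, `frac_viewing`, `viewing`; attributes `fps`, `epoch_s`,
#'   `total_viewing_s`.
#' @export
epoch_smooth <- function(log, epoch_s) {
  fps <- attr(log, "fps")
  if (epoch_s * fps < 1) {
    abort("`epoch_s * fps` must be at least 1 frame",
          class = "gazewatch_pipeline_error")
  }
  ep <- floor(log$frame_index / (epoch_s * fps))
  agg <- tibble::tibble(epoch = ep, viewing = log$viewing) %>%
    dplyr::group_by(.data$epoch) %>%
    dplyr::summarise(n_frames = dplyr::n(),
                     frac_viewing = mean(.data$viewing), .groups = "drop")
  agg$start_frame <- as.integer(cumsum(c(0L, head(agg$n_frames, -1))))
  agg$viewing <- agg$frac_viewing >= 0.5
  agg <- agg[, c("epoch", "start_frame", "n_frames", "frac_viewing", "viewing")]
  total <- sum(agg$viewing * agg$n_frames) / fps
  structure(agg, class = c("gw_epoch_log", class(agg)),
            fps = fps, epoch_s = epoch_s, total_viewing_s = total)
}

#' @export
print.gw_epoch_log <- function(x, ...) {
  cat(sprintf("<epoch log> %d epochs of %g s; viewing %s\n",
              nrow(x), attr(x, "epoch_s"),
              format_mmss(attr(x, "total_viewing_s"))))
  NextMethod()
}

#' Gold-standard viewing log of a simulated session
#'
#' The per-frame indicator of the gold code `watching` (frames coded
#' `out_of_frame`, `not_watching` or `cannot_tell` are not viewing
#' frames), as a `gw_viewing_log` for direct comparison with the pipeline
#' output.
#'
#' @param session A `gw_session`.
#' @return A `gw_viewing_log`.
#' @export
gold_viewing_log <- function(session) {
  codes <- expand_gold(session$gold, session$n_frames)
  viewing_log(codes == "watching", session$fps)
}
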