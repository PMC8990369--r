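# Face-detection harness: score thresholding, IoU matching against gold
# boxes, ROC construction and operating-point selection.
#
# True negatives are not meaningful for a face detector (they would be
# "everything that is not a face"), so detection is evaluated by
# sensitivity, positive predictive value and false positives per second of
# recording only.

#' Intersection-over-union of axis-aligned boxes
#'
#' Boxes use frame coordinates: `(x, y)` top-left corner, `x` rightward,
#' `y` downward, with positive width/height.
#'
#' @param a,b Matrices (or data frames) with columns `x, y, w, h`; `a` has
#'   m rows and `b` n rows.
#' @return An m x n matrix of IoU values in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  a <- as.matrix(as.data.frame(a)[, c("x", "y", "w", "h")])
  b <- as.matrix(as.data.frame(b)[, c("x", "y", "w", "h")])
  m <- nrow(a); n <- nrow(b)
  out <- matrix(0, m, n)
  if (m == 0 || n == 0) return(out)
  ax2 <- a[, 1] + a[, 3]; ay2 <- a[, 2] + a[, 4]
  bx2 <- b[, 1] + b[, 3]; by2 <- b[, 2] + b[, 4]
  for (j in seq_len(n)) {
    ix <- pmax(0, pmin(ax2, bx2[j]) - pmax(a[, 1], b[j, 1]))
    iy <- pmax(0, pmin(ay2, by2[j]) - pmax(a[, 2], b[j, 2]))
    inter <- ix * iy
    out[, j] <- inter / (a[, 3] * a[, 4] + b[j, 3] * b[j, 4] - inter)
  }
  out
}

#' Threshold candidate faces on detector confidence
#'
#' Keeps exactly the faces whose score is at least `tau_d`, preserving
#' order. This is the only decision the detection stage itself makes; the
#' threshold is normally chosen on an ROC with
#' [select_operating_point()].
#'
#' @param faces Tibble of candidate faces with a `score` column in \[0, 1\].
#' @param tau_d Score threshold in \[0, 1\].
#' @return The filtered tibble.
#' @export
apply_threshold <- function(faces, tau_d) {
  if (!is.numeric(tau_d) || length(tau_d) != 1 || tau_d < 0 || tau_d > 1) {
    abort("`tau_d` must be a single number in [0, 1]",
          class = "gazewatch_detection_error")
  }
  faces[faces$score >= tau_d, , drop = FALSE]
}

#' Match predicted boxes to gold boxes within one frame
#'
#' Greedy one-to-one matching in descending IoU order: the highest-IoU
#' (pred, gold) pair is matched first, both boxes are removed, and the
#' process repeats while the best remaining IoU is at least `iou_min`.
#' Matched pairs are true positives; unmatched predictions are false
#' positives; unmatched gold boxes are false negatives.
#'
#' @param pred,gold Tibbles of boxes (`x, y, w, h`), one frame each.
#' @param iou_min Minimum IoU for a valid match, in (0, 1\].
#' @return A list with `matches` (tibble: `pred_row`, `gold_row`, `iou`),
#'   `unmatched_pred` and `unmatched_gold` (integer row indices).
#' @export
match_to_gold <- function(pred, gold, iou_min = 0.5) {
  if (!is.numeric(iou_min) || iou_min <= 0 || iou_min > 1) {
    abort("`iou_min` must lie in (0, 1]", class = "gazewatch_detection_error")
  }
  m <- nrow(pred); n <- nrow(gold)
  iou <- box_iou(pred, gold)
  pr <- integer(0); gr <- integer(0); iv <- numeric(0)
  if (m > 0 && n > 0) {
    repeat {
      best <- which.max(iou)
      if (length(best) == 0 || iou[best] < iou_min) break
      i <- (best - 1) %% m + 1; j <- (best - 1) %/% m + 1
      pr <- c(pr, i); gr <- c(gr, j); iv <- c(iv, iou[best])
      iou[i, ] <- -1; iou[, j] <- -1
    }
  }
  list(
    matches = tibble::tibble(pred_row = pr, gold_row = gr, iou = iv),
    unmatched_pred = setdiff(seq_len(m), pr),
    unmatched_gold = setdiff(seq_len(n), gr)
  )
}

# per-frame confusion tallies of a set of predictions against gold people
detection_tally <- function(pred, gold, iou_min) {
  frames <- union(unique(pred$frame_index), unique(gold$frame_index))
  tp <- fp <- fn <- 0L
  pred_s <- split(pred, factor(pred$frame_index, levels = frames))
  gold_s <- split(gold, factor(gold$frame_index, levels = frames))
  for (k in seq_along(frames)) {
    m <- match_to_gold(pred_s[[k]], gold_s[[k]], iou_min)
    tp <- tp + nrow(m$matches)
    fp <- fp + length(m$unmatched_pred)
    fn <- fn + length(m$unmatched_gold)
  }
  c(tp = tp, fp = fp, fn = fn)
}

#' Build a detector ROC over score thresholds
#'
#' For each threshold, predictions with score at or above the threshold are
#' matched one-to-one to the gold boxes per frame; sensitivity is
#' TP / (TP + FN) over all gold faces and the false-positive rate is total
#' false positives divided by the total recording time
#' (`n_frames / fps` seconds, counting every frame whether or not it
#' contains a face).
#'
#' @param faces Candidate-face tibble with `frame_index`, boxes and `score`.
#' @param gold_people Gold-box tibble (`frame_index`, `x, y, w, h`).
#' @param thresholds Numeric vector of score thresholds.
#' @param fps Frames per second of the recording.
#' @param n_frames Total frame count (defaults to max frame index + 1).
#' @param iou_min IoU required for a match (default 0.5).
#' @return A tibble of class `"gw_roc"` with columns `threshold`
#'   (strictly decreasing), `sensitivity`, `fp_per_s`.
#' @export
build_roc <- function(faces, gold_people, thresholds, fps,
                      n_frames = NULL, iou_min = 0.5) {
  if (length(thresholds) == 0) {
    abort("`thresholds` must be non-empty", class = "gazewatch_detection_error")
  }
  if (nrow(gold_people) == 0) {
    abort("ROC undefined: no gold faces (sensitivity has a zero denominator)",
          class = "gazewatch_detection_error")
  }
  if (is.null(n_frames)) {
    n_frames <- max(c(faces$frame_index, gold_people$frame_index)) + 1
  }
  total_s <- n_frames / fps
  thresholds <- sort(unique(thresholds), decreasing = TRUE)
  rows <- lapply(thresholds, function(tau) {
    tl <- detection_tally(apply_threshold(faces, tau), gold_people, iou_min)
    tibble::tibble(threshold = tau,
                   sensitivity = tl[["tp"]] / (tl[["tp"]] + tl[["fn"]]),
                   fp_per_s = tl[["fp"]] / total_s)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gw_roc", class(out))
  out
}

#' Select a detector operating point on an ROC
#'
#' Returns the largest threshold whose sensitivity is at least
#' `min_sensitivity` and whose false-positive rate is at most `max_fps`.
#' If no row satisfies both, the sensitivity requirement is relaxed and the
#' threshold maximising sensitivity subject to the FP/s cap is returned
#' (the design intent: accept more false positives rather than miss faces,
#' since the verification stage screens impostors out). If the cap itself
#' is unattainable, an error lists the attainable frontier.
#'
#' @param roc A [build_roc()] table.
#' @param min_sensitivity Required sensitivity (default 0.925).
#' @param max_fps Maximum tolerated false positives per second
#'   (default 0.79).
#' @return The selected threshold (scalar), with the matching ROC row
#'   attached as attribute `"row"`.
#' @export
select_operating_point <- function(roc, min_sensitivity = 0.925,
                                   max_fps = 0.79) {
  if (nrow(roc) == 0) {
    abort("empty ROC table", class = "gazewatch_detection_error")
  }
  capped <- roc[roc$fp_per_s <= max_fps, , drop = FALSE]
  if (nrow(capped) == 0) {
    frontier <- paste(sprintf("(threshold %.3g: sens %.3f, fp/s %.3g)",
                              roc$threshold, roc$sensitivity, roc$fp_per_s),
                      collapse = ", ")
    abort(paste0("no threshold satisfies fp_per_s <= ", max_fps,
                 "; attainable frontier: ", frontier),
          class = "gazewatch_detection_error")
  }
  ok <- capped[capped$sensitivity >= min_sensitivity, , drop = FALSE]
  row <- if (nrow(ok) > 0) {
    ok[which.max(ok$threshold), ]
  } else {
    best <- capped[capped$sensitivity == max(capped$sensitivity), , drop = FALSE]
    best[which.max(best$threshold), ]
  }
  structure(row$threshold, row = row)
}

#' Evaluate detection against gold boxes
#'
#' Reports sensitivity, positive predictive value and false positives per
#' second -- overall and, when a gold log is supplied, restricted to frames
#' gold-coded `watching` and `not_watching` (accuracy, specificity and NPV
#' are not reported: true negatives are not meaningful for detection).
#' A stratum with no gold faces reports `NA` (undefined), never 0.
#'
#' @param pred Predicted (already thresholded) face tibble.
#' @param gold_people Gold-box tibble.
#' @param fps Frames per second.
#' @param n_frames Total frames (defaults to max frame index + 1).
#' @param gold_log Optional duration-coded gold log used to stratify frames
#'   by the target child's gaze code.
#' @param iou_min IoU required for a match.
#' @return A tibble with columns `stratum`, `tp`, `fp`, `fn`,
#'   `sensitivity`, `ppv`, `fp_per_s`, `n_seconds`.
#' @export
evaluate_detection <- function(pred, gold_people, fps, n_frames = NULL,
                               gold_log = NULL, iou_min = 0.5) {
  if (is.null(n_frames)) {
    n_frames <- max(c(pred$frame_index, gold_people$frame_index, 0)) + 1
  }
  strata <- list(overall = seq_len(n_frames) - 1L)
  if (!is.null(gold_log)) {
    codes <- expand_gold(gold_log, n_frames)
    strata$watching <- which(codes == "watching") - 1L
    strata$not_watching <- which(codes == "not_watching") - 1L
  }
  rows <- purrr::imap(strata, function(fr, nm) {
    p <- pred[pred$frame_index %in% fr, , drop = FALSE]
    g <- gold_people[gold_people$frame_index %in% fr, , drop = FALSE]
    tl <- detection_tally(p, g, iou_min)
    secs <- length(fr) / fps
    tibble::tibble(
      stratum = nm,
      tp = tl[["tp"]], fp = tl[["fp"]], fn = tl[["fn"]],
      sensitivity = if (tl[["tp"]] + tl[["fn"]] > 0)
        tl[["tp"]] / (tl[["tp"]] + tl[["fn"]]) else NA_real_,
      ppv = if (tl[["tp"]] + tl[["fp"]] > 0)
        tl[["tp"]] / (tl[["tp"]] + tl[["fp"]]) else NA_real_,
      fp_per_s = if (secs > 0) tl[["fp"]] / secs else NA_real_,
      n_seconds = secs
    )
  })
  dplyr::bind_rows(rows)
}

#' Fraction of detection false positives screened out by verification
#'
#' Among thresholded candidate faces that are detection false positives
#' (spurious boxes, `true_identity == "none"`), computes the fraction that
#' the verification stage rejects. The pipeline's effective false-positive
#' rate is then `(1 - screened) * detection FP/s`; see
#' [effective_fp_rate()].
#'
#' @param faces Thresholded candidate-face tibble with `true_identity`.
#' @param verified Logical vector: per face, did verification accept it as
#'   the target?
#' @return A list with `n_fp`, `n_passed`, `screened_fraction`.
#' @export
screening_fraction <- function(faces, verified) {
  stopifnot(length(verified) == nrow(faces))
  is_fp <- faces$true_identity == "none"
  n_fp <- sum(is_fp)
  n_passed <- sum(is_fp & verified)
  list(n_fp = n_fp, n_passed = n_passed,
       screened_fraction = if (n_fp > 0) 1 - n_passed / n_fp else NA_real_)
}

#' Effective false-positive rate after verification screening
#'
#' A detector operating at `fp_per_s` false positives per second, followed
#' by a verification stage that screens out a fraction `screened` of those
#' false positives, yields an effective rate of
#' `fp_per_s * (1 - screened)` spurious target detections per second.
#'
#' @param fp_per_s Detection false positives per second.
#' @param screened Fraction screened out by verification, in \[0, 1\].
#' @return Effective false positives per second.
#' @export
#' @examples
#' effective_fp_rate(0.79, 0.96)  # ~0.03 FP/s
effective_fp_rate <- function(fp_per_s, screened) {
  stopifnot(fp_per_s >= 0, screened >= 0, screened <= 1)
  fp_per_s * (1 - screened)
}
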