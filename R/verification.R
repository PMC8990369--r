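# Target-child verification: correlation match scores against an
# enrollment gallery, thresholding, IoU track building and temporal
# identity smoothing.

#' Match score of an embedding against a gallery
#'
#' The match score is the Pearson correlation between a candidate face
#' embedding and each gallery embedding, aggregated by the maximum over
#' gallery rows (robust to pose-diverse enrollment). Scores close to 1
#' indicate the same person.
#'
#' @param embedding Numeric vector (same length as gallery columns).
#' @param gallery Matrix of enrollment embeddings, one per row.
#' @return A score in \[-1, 1\].
#' @export
#' @examples
#' g <- matrix(rnorm(20), 2, 10)
#' g <- g / sqrt(rowSums(g^2))
#' match_score(g[1, ], g)  # 1
match_score <- function(embedding, gallery) {
  gallery <- as.matrix(gallery)
  if (length(embedding) != ncol(gallery)) {
    abort("embedding dimension does not match gallery",
          class = "gazewatch_verify_error")
  }
  if (var(embedding) == 0 || any(apply(gallery, 1, var) == 0)) {
    abort("zero-variance vector: correlation match score undefined",
          class = "gazewatch_verify_error")
  }
  max(as.numeric(cor(embedding, t(gallery))))
}

# vectorised match scores for a faces tibble (max Pearson r over gallery)
match_scores <- function(faces, gallery) {
  if (nrow(faces) == 0) return(numeric(0))
  emb <- matrix(unlist(faces$embedding), nrow = nrow(faces), byrow = TRUE)
  if (ncol(emb) != ncol(gallery)) {
    abort("embedding dimension does not match gallery",
          class = "gazewatch_verify_error")
  }
  if (any(apply(as.matrix(gallery), 1, var) == 0)) {
    abort("zero-variance gallery row: correlation undefined",
          class = "gazewatch_verify_error")
  }
  v <- apply(emb, 1, var)
  if (any(v == 0)) {
    abort("zero-variance embedding: correlation undefined",
          class = "gazewatch_verify_error")
  }
  apply(cor(t(emb), t(as.matrix(gallery))), 1, max)
}

#' Pick the target face in one frame
#'
#' Among faces whose match score reaches `tau_v`, returns the index of the
#' highest-scoring one (ties break to the lowest face index), or `NA` if no
#' face passes: at most one target per frame.
#'
#' @param scores Numeric vector of per-face match scores for one frame.
#' @param tau_v Match-score threshold in (-1, 1); default 0.93.
#' @return Integer index into `scores`, or `NA_integer_`.
#' @export
verify_frame <- function(scores, tau_v = 0.93) {
  if (tau_v <= -1 || tau_v >= 1) {
    abort("`tau_v` must lie in (-1, 1)", class = "gazewatch_verify_error")
  }
  pass <- which(scores >= tau_v)
  if (length(pass) == 0) return(NA_integer_)
  pass[which.max(scores[pass])]  # which.max takes the first maximum
}

#' Associate detections across frames into tracks
#'
#' Greedy frame-to-frame association: each box in frame t is linked to the
#' unclaimed track whose most recent box (within `max_gap` frames) has the
#' highest IoU, provided it reaches `iou_assoc`; unassociated boxes start
#' new tracks. Exploits the continuity of identity across successive
#' frames.
#'
#' @param faces Candidate-face tibble ordered by `frame_index`, with box
#'   columns `x, y, w, h`.
#' @param iou_assoc Minimum IoU to extend a track (default 0.3).
#' @param max_gap Number of missing frames a track survives (default 0:
#'   a track ends as soon as one frame passes without a match).
#' @return Integer vector of track ids aligned with `faces` rows.
#' @export
build_tracks <- function(faces, iou_assoc = 0.3, max_gap = 0L) {
  n <- nrow(faces)
  track <- integer(n)
  if (n == 0) return(track)
  if (is.unsorted(faces$frame_index)) {
    abort("`faces` must be ordered by frame_index",
          class = "gazewatch_verify_error")
  }
  bx <- faces$x; by <- faces$y; bw <- faces$w; bh <- faces$h
  fi <- faces$frame_index
  idx_by_frame <- split(seq_len(n), fi)
  frames <- as.integer(names(idx_by_frame))

  next_id <- 0L
  # active tracks: parallel vectors of last box + id + last frame
  act_x <- act_y <- act_w <- act_h <- numeric(0)
  act_id <- act_f <- integer(0)

  for (k in seq_along(frames)) {
    f <- frames[k]
    rows <- idx_by_frame[[k]]
    alive <- act_f >= f - 1L - max_gap
    act_x <- act_x[alive]; act_y <- act_y[alive]
    act_w <- act_w[alive]; act_h <- act_h[alive]
    act_id <- act_id[alive]; act_f <- act_f[alive]

    na <- length(act_id); nc <- length(rows)
    assigned <- rep(NA_integer_, nc)
    if (na > 0) {
      iou <- box_iou(cbind(x = bx[rows], y = by[rows], w = bw[rows], h = bh[rows]),
                     cbind(x = act_x, y = act_y, w = act_w, h = act_h))
      repeat {
        best <- which.max(iou)
        if (length(best) == 0 || iou[best] < iou_assoc) break
        i <- (best - 1) %% nc + 1; j <- (best - 1) %/% nc + 1
        assigned[i] <- j
        iou[i, ] <- -1; iou[, j] <- -1
      }
    }
    for (i in seq_len(nc)) {
      r <- rows[i]
      if (!is.na(assigned[i])) {
        j <- assigned[i]
        track[r] <- act_id[j]
        act_x[j] <- bx[r]; act_y[j] <- by[r]
        act_w[j] <- bw[r]; act_h[j] <- bh[r]
        act_f[j] <- f
      } else {
        next_id <- next_id + 1L
        track[r] <- next_id
        act_x <- c(act_x, bx[r]); act_y <- c(act_y, by[r])
        act_w <- c(act_w, bw[r]); act_h <- c(act_h, bh[r])
        act_id <- c(act_id, next_id); act_f <- c(act_f, f)
      }
    }
  }
  track
}

#' Smooth identity decisions along a track
#'
#' Each position's smoothed decision is the majority of the raw
#' (thresholded) decisions in a centred window of `window_frames`
#' positions, clipped to the track ends; exact ties resolve to the raw
#' decision at that position.
#'
#' @param raw Logical vector of raw per-frame decisions along one track.
#' @param window_frames Odd window length >= 1.
#' @return Logical vector of smoothed decisions, same length.
#' @export
#' @examples
#' smooth_identity(c(TRUE, TRUE, FALSE, TRUE, TRUE), 5)
smooth_identity <- function(raw, window_frames = 15L) {
  if (window_frames < 1 || window_frames %% 2 == 0) {
    abort("`window_frames` must be odd and >= 1",
          class = "gazewatch_verify_error")
  }
  n <- length(raw)
  if (n == 0) return(logical(0))
  half <- (window_frames - 1) / 2
  cs <- c(0, cumsum(as.numeric(raw)))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  pos <- cs[hi + 1] - cs[lo]
  size <- hi - lo + 1
  out <- pos * 2 > size
  tie <- pos * 2 == size
  out[tie] <- raw[tie]
  out
}

#' Verify the target child across a session
#'
#' Runs the full verification stage on (already thresholded) candidate
#' faces: match scores against the gallery, raw threshold decisions,
#' IoU-based track building, majority smoothing of decisions within each
#' track, and a final per-frame argmax so that at most one face per frame
#' is declared the target.
#'
#' @param faces Candidate-face tibble (ordered by `frame_index`).
#' @param gallery Enrollment gallery matrix.
#' @param tau_v Match-score threshold (default 0.93).
#' @param window_frames Odd smoothing window in frames (default 15,
#'   about one second at 15 fps).
#' @param iou_assoc Track association IoU (default 0.3).
#' @return The input tibble with added columns `score_match`, `track`,
#'   `raw_target` (threshold decision), `smoothed_target` (after majority
#'   smoothing) and `is_target` (final, at most one per frame).
#' @export
verify_session <- function(faces, gallery, tau_v = 0.93,
                           window_frames = 15L, iou_assoc = 0.3) {
  if (tau_v <= -1 || tau_v >= 1) {
    abort("`tau_v` must lie in (-1, 1)", class = "gazewatch_verify_error")
  }
  faces <- faces[order(faces$frame_index), , drop = FALSE]
  if (nrow(faces) == 0) {
    faces$score_match <- numeric(0); faces$track <- integer(0)
    faces$raw_target <- faces$smoothed_target <- faces$is_target <- logical(0)
    return(faces)
  }
  faces$score_match <- match_scores(faces, gallery)
  faces$track <- build_tracks(faces, iou_assoc = iou_assoc)
  faces$raw_target <- faces$score_match >= tau_v
  sm <- logical(nrow(faces))
  for (ids in split(seq_len(nrow(faces)), faces$track)) {
    sm[ids] <- smooth_identity(faces$raw_target[ids], window_frames)
  }
  faces$smoothed_target <- sm

  # per-frame argmax among smoothed positives (ties -> lowest face index)
  is_t <- logical(nrow(faces))
  cand <- which(faces$smoothed_target)
  if (length(cand)) {
    o <- cand[order(faces$frame_index[cand], -faces$score_match[cand],
                    faces$face[cand])]
    keep <- o[!duplicated(faces$frame_index[o])]
    is_t[keep] <- TRUE
  }
  faces$is_target <- is_t
  faces
}

#' Evaluate verification decisions against true identities
#'
#' Face-box-level confusion counting (positive = declared target), with
#' accuracy, sensitivity, specificity, PPV and NPV, overall and stratified
#' by the gold gaze code of the frame. Empty strata report `NA`
#' (undefined), never 0.
#'
#' @param faces Verified face tibble from [verify_session()] (needs
#'   `is_target` and `true_identity`).
#' @param gold_log Optional gold log for gaze stratification.
#' @param n_frames Frame count (needed with `gold_log`).
#' @return Tibble with one row per stratum: counts and Table-2-style
#'   metrics.
#' @export
evaluate_verification <- function(faces, gold_log = NULL, n_frames = NULL) {
  strata <- list(overall = rep(TRUE, nrow(faces)))
  if (!is.null(gold_log)) {
    stopifnot(!is.null(n_frames))
    codes <- expand_gold(gold_log, n_frames)
    fc <- codes[faces$frame_index + 1L]
    strata$watching <- fc == "watching"
    strata$not_watching <- fc == "not_watching"
  }
  rows <- purrr::imap(strata, function(sel, nm) {
    f <- faces[sel, , drop = FALSE]
    truth <- f$true_identity == "target"
    decl <- f$is_target
    cc <- confusion_counts(decl, truth)
    dplyr::bind_cols(tibble::tibble(stratum = nm),
                     tibble::as_tibble(as.list(cc)),
                     metrics_from_counts(cc))
  })
  dplyr::bind_rows(rows)
}
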