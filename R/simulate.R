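# Synthetic multi-person viewing sessions with known ground truth.
#
# The simulator emulates a laboratory/home observation: up to three people
# (target child, sibling, parent) sit in front of a large screen with a
# camera on top of it. Each frame yields candidate face boxes with detector
# confidence scores, unit-norm identity embeddings and unit gaze direction
# vectors; a duration-coded gold log records the target child's true state.
#
# Camera model (synthetic): the camera sits at the top-centre of the screen
# box. Pixels map to 3-D rays through a pinhole with focal length 600 px;
# people sit at fixed depths. Gaze vectors are reported in a camera-facing
# frame (x right, y down, z from the scene toward the camera/display
# plane), so a child looking straight at the camera has gaze (0, 0, 1) and
# screen-directed gaze has small yaw/pitch.

GW_FOCAL_PX <- 600       # pinhole focal length, pixels
GW_SCREEN_PX_PER_M <- 400  # pixel scale of the screen plane at the camera

# --- geometry helpers --------------------------------------------------------

camera_pixel <- function(config) {
  sb <- config$screen_box
  c(sb[1] + sb[3] / 2, sb[2])
}

# 3-D coordinates (camera frame, z into scene) of the screen centre/corners
screen_points_3d <- function(config) {
  sb <- config$screen_box
  cam <- camera_pixel(config)
  px <- c(sb[1] + sb[3] / 2, sb[1], sb[1] + sb[3], sb[1], sb[1] + sb[3])
  py <- c(sb[2] + sb[4] / 2, sb[2], sb[2], sb[2] + sb[4], sb[2] + sb[4])
  cbind(x = (px - cam[1]) / GW_SCREEN_PX_PER_M,
        y = (py - cam[2]) / GW_SCREEN_PX_PER_M,
        z = 0)
}

# exact gaze angles (degrees) from a face at pixel (cx, cy), depth z_m,
# toward a screen point; returns cbind(yaw, pitch) in the camera-facing frame
face_to_point_angles <- function(cx, cy, z_m, point3d, config) {
  cam <- camera_pixel(config)
  fx <- (cx - cam[1]) * z_m / GW_FOCAL_PX
  fy <- (cy - cam[2]) * z_m / GW_FOCAL_PX
  mx <- point3d[1] - fx
  my <- point3d[2] - fy
  mz <- z_m  # z toward camera: face depth minus screen depth (0)
  yaw <- atan2(mx, mz) * 180 / pi
  pitch <- atan2(-my, sqrt(mx^2 + mz^2)) * 180 / pi
  cbind(yaw = yaw, pitch = pitch)
}

#' Exact face-to-screen-centre gaze angles
#'
#' Returns the yaw/pitch (degrees) of the exact direction from a face at
#' frame position `(cx, cy)` and depth `depth_m` toward the screen-box
#' centre, under the simulator's camera model. Useful as an independent
#' reference when checking fitted angular limits.
#'
#' @param cx,cy Face-box centre, pixels.
#' @param depth_m Distance of the face from the camera, metres.
#' @param config A [session_config()].
#' @return A tibble with columns `yaw`, `pitch` (degrees).
#' @export
face_screen_angles <- function(cx, cy, depth_m, config) {
  sp <- screen_points_3d(config)
  a <- face_to_point_angles(cx, cy, depth_m, sp[1, ], config)
  tibble::tibble(yaw = a[, "yaw"], pitch = a[, "pitch"])
}

# angular half-extent (degrees) of the screen seen from a face position
screen_half_extent_deg <- function(cx, cy, z_m, config) {
  sp <- screen_points_3d(config)
  ctr <- face_to_point_angles(cx, cy, z_m, sp[1, ], config)
  v0 <- angles_to_gaze(ctr[, "yaw"], ctr[, "pitch"])
  worst <- rep(0, length(cx))
  for (k in 2:5) {
    ak <- face_to_point_angles(cx, cy, z_m, sp[k, ], config)
    vk <- angles_to_gaze(ak[, "yaw"], ak[, "pitch"])
    d <- acos(pmin(1, pmax(-1, rowSums(v0 * vk)))) * 180 / pi
    worst <- pmax(worst, d)
  }
  worst
}

# reflect a random walk into [-range, range]
reflect_walk <- function(steps, range) {
  v <- cumsum(steps)
  if (range <= 0) return(rep(0, length(v)))
  y <- (v + range) %% (4 * range)
  ifelse(y > 2 * range, 4 * range - y, y) - range
}

# two-state chain driven by pre-drawn uniforms; returns logical (watching)
markov_chain <- function(u, init_watching, p_wn, p_nw) {
  n <- length(u)
  s <- logical(n)
  cur <- init_watching
  for (i in seq_len(n)) {
    cur <- if (cur) u[i] >= p_wn else u[i] < p_nw
    s[i] <- cur
  }
  # note: state at frame 1 already allows one transition from the initial
  # state; prepend semantics: frame 0 state IS the initial state
  c(init_watching, s[-n])
}

# --- gold-log run-length coding ---------------------------------------------

#' Run-length encode per-frame gold codes
#'
#' Converts a per-frame character vector of codes into duration-coded runs
#' over half-open frame intervals `[start_frame, end_frame)`, the storage
#' form of a gold log. Consecutive equal codes merge into one run.
#'
#' @param codes Character vector, one code per frame (frames 0-based).
#' @return A tibble with columns `code`, `start_frame`, `end_frame`.
#' @seealso [expand_gold()]
#' @export
encode_gold <- function(codes) {
  stopifnot(length(codes) > 0)
  r <- rle(codes)
  ends <- cumsum(r$lengths)
  tibble::tibble(code = r$values,
                 start_frame = as.integer(c(0L, head(ends, -1))),
                 end_frame = as.integer(ends))
}

#' Expand a duration-coded gold log to per-frame codes
#'
#' @param gold A gold-log tibble (`code`, `start_frame`, `end_frame`) whose
#'   runs tile `[0, n_frames)` without gap or overlap.
#' @param n_frames Total number of frames.
#' @return Character vector of length `n_frames`.
#' @export
expand_gold <- function(gold, n_frames) {
  lens <- gold$end_frame - gold$start_frame
  if (any(lens <= 0) || gold$start_frame[1] != 0L ||
      tail(gold$end_frame, 1) != n_frames ||
      (nrow(gold) > 1 && any(gold$start_frame[-1] != head(gold$end_frame, -1)))) {
    abort("gold runs must tile [0, n_frames) without overlap or gap",
          class = "gazewatch_gold_error")
  }
  rep(gold$code, lens)
}

#' Inject coder disagreement into a gold log
#'
#' Flips each frame's code, independently with probability `error_rate`, to
#' a code drawn uniformly from the other three categories. Intended for
#' exercising interrater agreement statistics (the simulator's own gold
#' codes are otherwise perfect).
#'
#' @param gold Gold-log tibble.
#' @param n_frames Number of frames the log covers.
#' @param error_rate Per-frame flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A gold-log tibble of the same form.
#' @export
corrupt_gold <- function(gold, n_frames, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  codes <- expand_gold(gold, n_frames)
  lvls <- c("watching", "not_watching", "out_of_frame", "cannot_tell")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  flip <- runif(n_frames) < error_rate
  if (any(flip)) {
    pick <- function(code) sample(setdiff(lvls, code), 1L)
    codes[flip] <- vapply(codes[flip], pick, character(1))
  }
  encode_gold(codes)
}

# --- simulator ---------------------------------------------------------------

#' Simulate a multi-person viewing session
#'
#' Generates a full synthetic session from a [session_config()]: a stream of
#' per-frame candidate faces (detector scores, identity embeddings, gaze
#' vectors, plus simulator-only ground-truth columns), the true face boxes
#' of every present person, and a duration-coded gold log for the target
#' child. Deterministic for a fixed configuration.
#'
#' The target child follows a two-state (watching / not watching) Markov
#' process and occasionally leaves the room; while out, frames are gold
#' coded `out_of_frame`. When watching, the emitted gaze vector is the
#' exact face-to-screen-centre direction perturbed by Gaussian yaw/pitch
#' noise (`gaze_noise_deg`, scaled by lighting); when not watching, the
#' gaze points to a random direction at least the screen's angular
#' half-extent plus `max(2 * gaze_noise_deg_effective, 10)` degrees away
#' from the screen centre, so the two classes stay separable as noise
#' vanishes. Embeddings are drawn around per-person identity centroids with
#' lighting-scaled noise; detector misses and confidence scores also degrade
#' with lighting.
#'
#' @param config A [session_config()].
#' @return An object of class `"gw_session"`: a list with elements
#'   \describe{
#'     \item{faces}{tibble of candidate faces: `frame_index` (0-based), `t`,
#'       `face` (1-based index within frame), box `x, y, w, h`, `score`,
#'       `embedding` (list-column of unit vectors), gaze components
#'       `gx, gy, gz`, and ground truth `true_identity`
#'       (`target`/`sibling`/`parent`/`none`), `true_gaze_on_tv`,
#'       `true_yaw`, `true_pitch` (exact screen-centre angles).}
#'     \item{people}{tibble of true face boxes of present persons (the gold
#'       boxes for detection evaluation).}
#'     \item{gold}{duration-coded gold log for the target child.}
#'     \item{n_frames, config}{bookkeeping.}
#'   }
#' @export
#' @examples
#' s <- simulate_session(session_config(duration_s = 20, seed = 42))
#' s
#' head(s$faces[, c("frame_index", "face", "score", "true_identity")])
simulate_session <- function(config) {
  if (!inherits(config, "session_config")) {
    abort("`config` must be a session_config object",
          class = "gazewatch_config_error")
  }
  mult <- lighting_multipliers(config$lighting)
  n_frames <- as.integer(round(config$duration_s * config$fps))
  fps <- config$fps
  np <- config$n_persons
  dim <- config$embedding_dim
  W <- config$frame_size[1]; H <- config$frame_size[2]
  persons <- c("target", "sibling", "parent")[seq_len(np)]

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  # 1. identity centroids (skipped draws if supplied)
  centroids <- config$centroids
  if (is.null(centroids)) {
    centroids <- make_centroids(dim, np, config$centroid_separation,
                                seed = config$seed + 104729L)
  } else {
    centroids <- centroids[seq_len(np), , drop = FALSE]
  }

  # 2. home positions: one x-slot per person (keeps boxes disjoint), free y
  usable <- c(0.08, 0.92) * W
  slot_w <- diff(usable) / np
  slot_centers <- usable[1] + (seq_len(np) - 0.5) * slot_w
  home_x <- slot_centers + runif(np, -10, 10)
  home_y <- runif(np, 0.25, 0.55) * H
  if (!is.null(config$home_xy)) {   # fixed seating shared across sessions
    home_x <- config$home_xy[seq_len(np), 1]
    home_y <- config$home_xy[seq_len(np), 2]
  }

  # 3. bounded random walks (draw counts independent of walk_sd)
  steps_x <- matrix(rnorm(n_frames * np), n_frames, np) * config$walk_sd
  steps_y <- matrix(rnorm(n_frames * np), n_frames, np) * config$walk_sd
  cx <- cy <- matrix(0, n_frames, np)
  for (p in seq_len(np)) {
    cx[, p] <- home_x[p] + reflect_walk(steps_x[, p], config$walk_range)
    cy[, p] <- home_y[p] + reflect_walk(steps_y[, p], config$walk_range)
  }

  # 4. room exits (target only)
  t_frame <- (seq_len(n_frames) - 1) / fps
  absent <- rep(FALSE, n_frames)
  if (config$p_exit > 0 && config$mean_exit_s > 0) {
    tt <- 0
    while (TRUE) {
      tt <- tt + rexp(1, config$p_exit)
      if (tt >= config$duration_s) break
      len <- rexp(1, 1 / config$mean_exit_s)
      absent <- absent | (t_frame >= tt & t_frame < tt + len)
      tt <- tt + len
    }
  }

  # 5. gaze states (per person, per-frame transition probabilities)
  p_wn <- 1 - (1 - config$p_watch_to_notwatch)^(1 / fps)
  p_nw <- 1 - (1 - config$p_notwatch_to_watch)^(1 / fps)
  denom <- config$p_watch_to_notwatch + config$p_notwatch_to_watch
  p_stat <- if (denom > 0) config$p_notwatch_to_watch / denom else 1
  u_init <- runif(np)
  u_state <- matrix(runif(n_frames * np), n_frames, np)
  watching <- matrix(FALSE, n_frames, np)
  for (p in seq_len(np)) {
    init <- if (p == 1L && !is.null(config$initial_state)) {
      config$initial_state == "watching"
    } else {
      u_init[p] < p_stat
    }
    watching[, p] <- markov_chain(u_state[, p], init, p_wn, p_nw)
  }

  # 6. coder "cannot tell" overlay
  u_ct <- runif(n_frames)

  # 7. detection misses and confidence scores
  u_miss <- matrix(runif(n_frames * np), n_frames, np)
  z_score <- matrix(rnorm(n_frames * np), n_frames, np)
  p_miss_eff <- min(1, config$p_miss * mult["miss"])
  penalty <- lighting_score_penalty(config$lighting)

  # presence: everyone but the target is always in the room
  present <- matrix(TRUE, n_frames, np)
  present[, 1] <- !absent

  # 8. spurious detections (count independent of lighting/noise settings)
  n_spur <- rpois(n_frames, config$fp_rate)
  k_spur <- sum(n_spur)
  spur_w <- runif(k_spur, 20, 80)
  spur_h <- spur_w * runif(k_spur, 0.9, 1.3)
  spur_x <- runif(k_spur) * pmax(1, W - spur_w)
  spur_y <- runif(k_spur) * pmax(1, H - spur_h)
  spur_score <- runif(k_spur, 0.5, 0.95)
  spur_emb <- matrix(rnorm(k_spur * dim), k_spur, dim)
  spur_emb <- spur_emb / sqrt(pmax(rowSums(spur_emb^2), 1e-12))
  spur_gaze <- matrix(rnorm(k_spur * 3), k_spur, 3)
  spur_gaze <- spur_gaze / sqrt(pmax(rowSums(spur_gaze^2), 1e-12))

  # 9. embedding noise for every present person-frame
  pres_idx <- which(present)                       # column-major (frame, person)
  n_pres <- length(pres_idx)
  emb_noise <- matrix(rnorm(n_pres * dim), n_pres, dim) *
    (config$embedding_noise_sd * mult["embed"])

  # 10. gaze measurement noise (yaw, pitch) for present person-frames
  sigma_eff <- config$gaze_noise_deg * mult["gaze"]
  gz_noise <- matrix(rnorm(n_pres * 2), n_pres, 2) * sigma_eff

  # assemble present person-frame table -----------------------------------
  pf_frame <- ((pres_idx - 1) %% n_frames) + 1L        # row in matrices
  pf_person <- ((pres_idx - 1) %/% n_frames) + 1L
  pf_cx <- cx[pres_idx]; pf_cy <- cy[pres_idx]
  pf_depth <- config$person_depth_m[pf_person]
  box_w <- round(70 * 2 / pf_depth)
  box_h <- round(box_w * 1.25)

  sp <- screen_points_3d(config)
  exact <- face_to_point_angles(pf_cx, pf_cy, pf_depth, sp[1, ], config)
  pf_watch <- watching[pres_idx]

  obs_yaw <- exact[, "yaw"]; obs_pitch <- exact[, "pitch"]
  obs_yaw[pf_watch] <- obs_yaw[pf_watch] + gz_noise[pf_watch, 1]
  obs_pitch[pf_watch] <- obs_pitch[pf_watch] + gz_noise[pf_watch, 2]
  gvec <- angles_to_gaze(obs_yaw, obs_pitch)

  # off-screen directions for non-watching person-frames (last RNG stage)
  nw <- which(!pf_watch)
  if (length(nw)) {
    half_ext <- screen_half_extent_deg(pf_cx[nw], pf_cy[nw], pf_depth[nw], config)
    excl <- (half_ext + pmax(2 * sigma_eff, 10)) * pi / 180
    v0 <- angles_to_gaze(exact[nw, "yaw"], exact[nw, "pitch"])
    dir <- matrix(0, length(nw), 3)
    todo <- seq_along(nw)
    while (length(todo)) {
      cand <- matrix(rnorm(length(todo) * 3), ncol = 3)
      cand <- cand / sqrt(pmax(rowSums(cand^2), 1e-12))
      ang <- acos(pmin(1, pmax(-1, rowSums(cand * v0[todo, , drop = FALSE]))))
      ok <- ang >= excl[todo]
      dir[todo[ok], ] <- cand[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
    gvec[nw, ] <- dir
  }

  # embeddings around centroids, re-normalised
  emb <- centroids[pf_person, , drop = FALSE] + emb_noise
  emb <- emb / sqrt(pmax(rowSums(emb^2), 1e-12))

  # detector output: drop missed faces
  detected <- u_miss[pres_idx] >= p_miss_eff
  score <- pmin(1, pmax(0, 0.9 - penalty + 0.04 * z_score[pres_idx]))

  people <- tibble::tibble(
    frame_index = pf_frame - 1L,
    person = persons[pf_person],
    x = pf_cx - box_w / 2, y = pf_cy - box_h / 2, w = box_w, h = box_h
  )

  keep <- which(detected)
  true_faces <- tibble::tibble(
    frame_index = pf_frame[keep] - 1L,
    x = (pf_cx - box_w / 2)[keep], y = (pf_cy - box_h / 2)[keep],
    w = box_w[keep], h = box_h[keep],
    score = score[keep],
    row = keep,
    true_identity = persons[pf_person[keep]],
    true_gaze_on_tv = pf_watch[keep],
    true_yaw = exact[keep, "yaw"], true_pitch = exact[keep, "pitch"],
    gx = gvec[keep, 1], gy = gvec[keep, 2], gz = gvec[keep, 3]
  )
  true_faces$embedding <- lapply(keep, function(i) emb[i, ])

  spur_faces <- tibble::tibble(
    frame_index = rep.int(seq_len(n_frames) - 1L, n_spur),
    x = spur_x, y = spur_y, w = spur_w, h = spur_h,
    score = spur_score,
    row = NA_integer_,
    true_identity = "none",
    true_gaze_on_tv = FALSE,
    true_yaw = NA_real_, true_pitch = NA_real_,
    gx = spur_gaze[, 1], gy = spur_gaze[, 2], gz = spur_gaze[, 3]
  )
  spur_faces$embedding <- lapply(seq_len(k_spur), function(i) spur_emb[i, ])

  faces <- dplyr::bind_rows(true_faces, spur_faces)
  faces <- faces[order(faces$frame_index, is.na(faces$row), faces$row), ]
  faces$row <- NULL
  faces$face <- stats::ave(seq_len(nrow(faces)), faces$frame_index,
                           FUN = seq_along)
  faces$t <- faces$frame_index / fps
  faces <- faces[, c("frame_index", "t", "face", "x", "y", "w", "h", "score",
                     "embedding", "gx", "gy", "gz",
                     "true_identity", "true_gaze_on_tv",
                     "true_yaw", "true_pitch")]

  # gold log for the target child
  codes <- ifelse(absent, "out_of_frame",
                  ifelse(watching[, 1] & !absent, "watching", "not_watching"))
  ct <- u_ct < config$p_cannot_tell
  codes[ct] <- "cannot_tell"

  structure(
    list(config = config, n_frames = n_frames, fps = fps,
         faces = tibble::as_tibble(faces), people = people,
         gold = encode_gold(codes)),
    class = "gw_session"
  )
}

#' @export
print.gw_session <- function(x, ...) {
  codes <- expand_gold(x$gold, x$n_frames)
  cat("<gw_session>\n")
  cat(sprintf("  %d frames at %g fps (%.1f s), %d candidate faces\n",
              x$n_frames, x$fps, x$n_frames / x$fps, nrow(x$faces)))
  tab <- table(factor(codes, c("watching", "not_watching",
                               "out_of_frame", "cannot_tell")))
  cat("  gold frames: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Enroll a target-child gallery
#'
#' Collects the embeddings of the target child's face from the earliest `k`
#' frames in which a target face was observed, emulating enrollment images
#' taken at the start of a study protocol.
#'
#' @param session A [simulate_session()] result (or any list with a `faces`
#'   tibble carrying `true_identity` and `embedding`).
#' @param k Number of enrollment embeddings.
#' @return A `k` x `embedding_dim` matrix with unit rows (class `matrix`).
#' @export
enroll_gallery <- function(session, k = 10L) {
  faces <- session$faces
  tgt <- faces[faces$true_identity == "target", ]
  tgt <- tgt[!duplicated(tgt$frame_index), ]
  if (nrow(tgt) < k) {
    abort(sprintf("cannot enroll %d embeddings: target present in only %d frames",
                  k, nrow(tgt)), class = "gazewatch_enroll_error")
  }
  tgt <- tgt[order(tgt$frame_index), ][seq_len(k), ]
  g <- do.call(rbind, tgt$embedding)
  rownames(g) <- NULL
  g
}
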