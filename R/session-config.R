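# Session configuration for the synthetic multi-person simulator.

#' Configure a synthetic viewing session
#'
#' Builds a validated configuration for [simulate_session()]. The defaults
#' describe a typical laboratory observation: a target child, a sibling and a
#' parent seated in front of a large screen, recorded at 15 frames/s under
#' bright lighting, with the child switching between watching and not
#' watching and occasionally leaving the room.
#'
#' @param n_persons Number of people in the room (1--3, in the order target,
#'   sibling, parent). Default 3.
#' @param duration_s Session length in seconds.
#' @param fps Frame rate, frames per second; must lie in \[15, 30\].
#' @param frame_size Integer vector `c(width, height)` in pixels.
#' @param tv_position One of `"center"`, `"left"`, `"other"`. For `"other"`
#'   a `screen_box` must be supplied.
#' @param screen_box Screen location in frame coordinates,
#'   `c(x_min, y_min, width, height)`. Defaults depend on `tv_position`.
#' @param embedding_dim Length of the face embedding vectors (>= 2).
#' @param centroid_separation Pairwise angular distance, in degrees, between
#'   identity centroids on the unit hypersphere.
#' @param embedding_noise_sd Per-coordinate dispersion of frame embeddings
#'   around the identity centroid (before re-normalisation), under bright
#'   lighting.
#' @param gaze_noise_deg Angular measurement noise (degrees, SD applied
#'   independently to yaw and pitch) of the observed gaze vector under
#'   bright lighting.
#' @param p_watch_to_notwatch,p_notwatch_to_watch Per-second switch rates of
#'   the two-state watching Markov process.
#' @param p_exit Per-second rate at which the target child leaves the room.
#' @param mean_exit_s Mean duration, seconds, of a room exit.
#' @param lighting `"bright"`, `"dim"` or `"dark"`. Lighting multiplies the
#'   detection miss probability, the embedding noise and the gaze noise by
#'   1, 2 and 4 respectively, and lowers detector confidence scores.
#' @param p_miss Base per-face per-frame probability that the detector
#'   misses a truly present face (bright lighting).
#' @param fp_rate Expected number of spurious (non-face) detections per
#'   frame emitted by the detector backend.
#' @param p_cannot_tell Per-frame probability that the human coder marks the
#'   frame "cannot tell" instead of the true code.
#' @param walk_sd Per-frame SD, pixels, of each person's bounded random walk.
#' @param walk_range Maximum excursion, pixels, from a person's home
#'   position (the walk reflects at this bound).
#' @param person_depth_m Distance of each person from the camera, metres
#'   (recycled to `n_persons`).
#' @param centroids Optional matrix of identity centroids
#'   (`n_persons` x `embedding_dim`, unit rows), e.g. from
#'   [make_centroids()], to share identities across sessions ("visits").
#'   If `NULL`, centroids are drawn from the session seed.
#' @param home_xy Optional `n_persons` x 2 matrix of home (seating)
#'   positions in frame pixels, shared across sessions of one family; if
#'   `NULL`, homes are drawn per seed (one horizontal slot per person,
#'   free vertical placement).
#' @param initial_state Optional initial gaze state of the target child,
#'   `"watching"` or `"not_watching"`; if `NULL` (default) the initial
#'   state is drawn from the chain's stationary distribution.
#' @param seed Integer random seed; the simulator is fully deterministic
#'   given the configuration.
#'
#' @return A list of class `"session_config"`.
#' @seealso [simulate_session()], [make_centroids()]
#' @export
#' @examples
#' cfg <- session_config(duration_s = 60, seed = 1)
#' cfg$fps
session_config <- function(n_persons = 3,
                           duration_s = 600,
                           fps = 15,
                           frame_size = c(640L, 480L),
                           tv_position = c("center", "left", "other"),
                           screen_box = NULL,
                           embedding_dim = 128,
                           centroid_separation = 45,
                           embedding_noise_sd = 0.016,
                           gaze_noise_deg = 10,
                           p_watch_to_notwatch = 0.02,
                           p_notwatch_to_watch = 0.011,
                           p_exit = 0.002,
                           mean_exit_s = 30,
                           lighting = c("bright", "dim", "dark"),
                           p_miss = 0.02,
                           fp_rate = 0.053,
                           p_cannot_tell = 0,
                           walk_sd = 1.5,
                           walk_range = 25,
                           person_depth_m = c(2, 2.2, 2.5),
                           centroids = NULL,
                           home_xy = NULL,
                           initial_state = NULL,
                           seed = 1L) {
  tv_position <- match.arg(tv_position)
  lighting <- match.arg(lighting)

  chk_num <- function(x, field, lo = -Inf, hi = Inf, len = 1L) {
    if (!is.numeric(x) || length(x) != len || any(!is.finite(x)) ||
        any(x < lo) || any(x > hi)) {
      abort(sprintf("invalid `%s`: must be numeric length %d in [%s, %s]",
                    field, len, format(lo), format(hi)),
            class = "gazewatch_config_error")
    }
    invisible(x)
  }
  chk_num(n_persons, "n_persons", 1, 3)
  chk_num(duration_s, "duration_s", 1e-9)
  chk_num(fps, "fps", 15, 30)
  chk_num(frame_size, "frame_size", 1, len = 2L)
  chk_num(embedding_dim, "embedding_dim", 2)
  chk_num(centroid_separation, "centroid_separation", 0, 180)
  chk_num(embedding_noise_sd, "embedding_noise_sd", 0)
  chk_num(gaze_noise_deg, "gaze_noise_deg", 0, 90)
  chk_num(p_watch_to_notwatch, "p_watch_to_notwatch", 0, 1)
  chk_num(p_notwatch_to_watch, "p_notwatch_to_watch", 0, 1)
  chk_num(p_exit, "p_exit", 0, 1)
  chk_num(mean_exit_s, "mean_exit_s", 0)
  chk_num(p_miss, "p_miss", 0, 1)
  chk_num(fp_rate, "fp_rate", 0)
  chk_num(p_cannot_tell, "p_cannot_tell", 0, 1)
  chk_num(walk_sd, "walk_sd", 0)
  chk_num(walk_range, "walk_range", 0)
  chk_num(seed, "seed")

  frame_size <- as.integer(round(frame_size))
  if (is.null(screen_box)) {
    if (tv_position == "other") {
      abort("invalid `screen_box`: tv_position \"other\" requires an explicit screen box",
            class = "gazewatch_config_error")
    }
    w <- frame_size[1]
    sb_w <- round(0.3 * w); sb_h <- round(0.25 * frame_size[2])
    sb_x <- if (tv_position == "center") round((w - sb_w) / 2) else round(0.03 * w)
    screen_box <- c(sb_x, frame_size[2] - sb_h, sb_w, sb_h)
  }
  chk_num(screen_box, "screen_box", len = 4L)
  if (screen_box[3] <= 0 || screen_box[4] <= 0 ||
      screen_box[1] < 0 || screen_box[2] < 0 ||
      screen_box[1] + screen_box[3] > frame_size[1] ||
      screen_box[2] + screen_box[4] > frame_size[2]) {
    abort("invalid `screen_box`: must lie inside the frame with positive size",
          class = "gazewatch_config_error")
  }

  person_depth_m <- rep_len(person_depth_m, n_persons)
  chk_num(person_depth_m, "person_depth_m", 0.5, len = as.integer(n_persons))

  if (!is.null(home_xy)) {
    home_xy <- as.matrix(home_xy)
    if (nrow(home_xy) < n_persons || ncol(home_xy) != 2 ||
        any(home_xy[, 1] < 0 | home_xy[, 1] > frame_size[1] |
              home_xy[, 2] < 0 | home_xy[, 2] > frame_size[2])) {
      abort("invalid `home_xy`: need n_persons x 2 positions inside the frame",
            class = "gazewatch_config_error")
    }
  }
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) < n_persons || ncol(centroids) != embedding_dim) {
      abort("invalid `centroids`: need an n_persons x embedding_dim matrix",
            class = "gazewatch_config_error")
    }
    nrm <- sqrt(rowSums(centroids^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      abort("invalid `centroids`: rows must be unit-norm",
            class = "gazewatch_config_error")
    }
  }

  structure(
    list(
      n_persons = as.integer(n_persons), duration_s = duration_s, fps = fps,
      frame_size = frame_size, tv_position = tv_position,
      screen_box = as.numeric(screen_box),
      embedding_dim = as.integer(embedding_dim),
      centroid_separation = centroid_separation,
      embedding_noise_sd = embedding_noise_sd,
      gaze_noise_deg = gaze_noise_deg,
      p_watch_to_notwatch = p_watch_to_notwatch,
      p_notwatch_to_watch = p_notwatch_to_watch,
      p_exit = p_exit, mean_exit_s = mean_exit_s,
      lighting = lighting, p_miss = p_miss, fp_rate = fp_rate,
      p_cannot_tell = p_cannot_tell,
      walk_sd = walk_sd, walk_range = walk_range,
      person_depth_m = person_depth_m,
      centroids = centroids,
      home_xy = home_xy,
      initial_state = if (is.null(initial_state)) NULL else
        match.arg(initial_state, c("watching", "not_watching")),
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  %d person(s), %.0f s at %g fps, frame %dx%d px\n",
              x$n_persons, x$duration_s, x$fps, x$frame_size[1], x$frame_size[2]))
  cat(sprintf("  tv: %s  screen box: [%g, %g, %g, %g]\n",
              x$tv_position, x$screen_box[1], x$screen_box[2],
              x$screen_box[3], x$screen_box[4]))
  cat(sprintf("  lighting: %s  gaze noise: %g deg  embedding noise sd: %g\n",
              x$lighting, x$gaze_noise_deg, x$embedding_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# lighting multipliers: (detection miss, embedding noise, gaze noise)
lighting_multipliers <- function(lighting) {
  switch(lighting,
         bright = c(miss = 1, embed = 1, gaze = 1),
         dim    = c(miss = 2, embed = 2, gaze = 2),
         dark   = c(miss = 4, embed = 4, gaze = 4))
}

# detector confidence penalty under degraded lighting
lighting_score_penalty <- function(lighting) {
  switch(lighting, bright = 0, dim = 0.08, dark = 0.16)
}

#' Identity centroids on the unit hypersphere
#'
#' Draws `n` unit vectors in `dim` dimensions with exact pairwise angular
#' separation `separation_deg`, for use as person identity centroids that
#' can be shared across simulated sessions (repeat visits of one family).
#'
#' The construction places the identities on a regular simplex blended with
#' a common direction: `c_i = a u + b v_i` with `u` orthogonal to the
#' orthonormalised simplex directions `v_i`, giving every pair the inner
#' product `cos(separation_deg)`.
#'
#' @param dim Embedding dimension.
#' @param n Number of identities (n <= dim).
#' @param separation_deg Pairwise angular separation in degrees; must
#'   satisfy `cos(separation_deg) >= -1/(n-1)` for n > 1.
#' @param seed Integer seed.
#' @return An `n` x `dim` matrix with unit rows.
#' @export
#' @examples
#' cc <- make_centroids(16, 3, 45, seed = 2)
#' round(tcrossprod(cc), 3)  # off-diagonals equal cos(45 deg)
make_centroids <- function(dim, n, separation_deg, seed = 1L) {
  stopifnot(n >= 1, dim >= n + 1)
  rho <- cos(separation_deg * pi / 180)
  if (n > 1 && rho < -1 / (n - 1) - 1e-12) {
    abort(sprintf("separation too large: cos(sep) must be >= -1/(n-1) = %.3f",
                  -1 / (n - 1)), class = "gazewatch_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  basis <- qr.Q(qr(matrix(rnorm(dim * (n + 1)), dim, n + 1)))
  if (n == 1) {
    return(matrix(basis[, 1], 1, dim))
  }
  u <- basis[, 1]
  e <- basis[, 2:(n + 1), drop = FALSE]
  # regular simplex vertices in the span of e: pairwise inner product -1/(n-1)
  s <- diag(n) - 1 / n
  v <- e %*% (s / sqrt(1 - 1 / n))  # columns: unit, pairwise -1/(n-1)
  b2 <- (1 - rho) / (1 + 1 / (n - 1))
  a <- sqrt(max(0, 1 - b2))
  cc <- t(a * u + sqrt(b2) * v)
  cc / sqrt(rowSums(cc^2))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
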