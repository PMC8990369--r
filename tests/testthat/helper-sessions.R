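# Shared fixtures: small sessions built in code, cached per test run.

# a configuration with every noise source switched off; the switch rates
# default to a faster mixing regime than the package defaults so that
# short fixtures almost surely contain both gaze states
noiseless_config <- function(duration_s = 60, seed = 1,
                             p_watch_to_notwatch = 0.05,
                             p_notwatch_to_watch = 0.05, ...) {
  session_config(duration_s = duration_s, seed = seed,
                 gaze_noise_deg = 0, embedding_noise_sd = 0,
                 p_miss = 0, p_cannot_tell = 0, embedding_dim = 32,
                 p_watch_to_notwatch = p_watch_to_notwatch,
                 p_notwatch_to_watch = p_notwatch_to_watch, ...)
}

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- simulate_session(config)
  }
  .session_cache[[key]]
}

# default-noise session reused across detection/verification tests
default_session <- function() {
  cached_session("default", session_config(duration_s = 60, seed = 42,
                                           p_watch_to_notwatch = 0.05,
                                           p_notwatch_to_watch = 0.05))
}

noiseless_session <- function() {
  cached_session("noiseless", noiseless_config(seed = 5))
}

# a family: enrollment session + measurement session sharing identities
simulate_family <- function(seed, duration_s = 60, lighting = "bright",
                            tv_position = "center", ...) {
  cc <- make_centroids(128, 3, 45, seed = seed + 7000)
  enroll <- simulate_session(session_config(
    duration_s = 20, seed = seed + 9000, centroids = cc,
    tv_position = tv_position))
  meas <- simulate_session(session_config(
    duration_s = duration_s, seed = seed, centroids = cc,
    lighting = lighting, tv_position = tv_position,
    p_watch_to_notwatch = 0.05, p_notwatch_to_watch = 0.05, ...))
  list(gallery = enroll_gallery(enroll, 10), session = meas)
}

# independent brute-force majority smoother (oracle for smooth_identity)
brute_majority <- function(raw, window) {
  n <- length(raw)
  half <- (window - 1) / 2
  out <- logical(n)
  for (i in seq_len(n)) {
    win <- raw[max(1, i - half):min(n, i + half)]
    npos <- sum(win)
    out[i] <- if (npos * 2 == length(win)) raw[i] else npos * 2 > length(win)
  }
  out
}

# independent exhaustive best one-to-one assignment by total IoU, subject
# to a minimum IoU per pair (oracle for greedy matching on small fixtures)
brute_best_assignment <- function(iou, iou_min) {
  m <- nrow(iou); n <- ncol(iou)
  best <- list(score = -Inf, pairs = cbind(integer(0), integer(0)))
  subsets <- function(total) unlist(lapply(0:min(m, n), function(k)
    if (k == 0) list(integer(0)) else utils::combn(total, k, simplify = FALSE)),
    recursive = FALSE)
  gold_sets <- subsets(n)
  pred_sets <- subsets(m)
  perm <- function(v) if (length(v) <= 1) list(v) else
    unlist(lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  for (ps in pred_sets) {
    k <- length(ps)
    if (k > n) next
    for (gs in gold_sets[vapply(gold_sets, length, 1L) == k]) {
      for (gp in perm(gs)) {
        vals <- iou[cbind(ps, gp)]
        if (k > 0 && any(vals < iou_min)) next
        sc <- sum(vals)
        if (sc > best$score ||
            (sc == best$score && k > nrow(best$pairs))) {
          best <- list(score = sc, pairs = cbind(ps, gp))
        }
      }
    }
  }
  best$pairs
}
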