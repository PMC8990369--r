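# Gaze stage: angle conversion, frame regions, angular-limit fitting,
# dichotomization and leave-one-family-out evaluation.

test_that("gaze angles follow the stated convention and round-trip", {
  a <- gaze_angles(c(0, 0, 1))
  expect_equal(c(a$yaw, a$pitch), c(0, 0))
  a <- gaze_angles(c(1, 0, 0))
  expect_equal(c(a$yaw, a$pitch), c(90, 0))
  a <- gaze_angles(c(0, -1, 0))  # y down: looking up
  expect_equal(a$pitch, 90)
  set.seed(5)
  v <- matrix(rnorm(300), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  ang <- gaze_angles(v)
  expect_equal(angles_to_gaze(ang$yaw, ang$pitch), v,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(gaze_angles(c(1, 1, 1)), class = "gazewatch_gaze_error")
})

test_that("frame regions are row-major with edge pixels in the last cell", {
  fsz <- c(640, 480)
  expect_identical(region_of(320, 240, fsz, c(3, 3)), 4L)
  expect_identical(region_of(0, 0, fsz, c(3, 3)), 0L)
  expect_identical(region_of(640, 480, fsz, c(3, 3)), 8L)
  expect_error(region_of(-1, 0, fsz), class = "gazewatch_gaze_error")
  # exhaustive sweep on a tiny frame vs floor-division arithmetic
  tiny <- c(12, 8); grid <- c(2, 4)
  for (px in 0:12) for (py in 0:8) {
    col <- min(grid[2] - 1, floor(px / tiny[1] * grid[2]))
    row <- min(grid[1] - 1, floor(py / tiny[2] * grid[1]))
    expect_identical(region_of(px, py, tiny, grid),
                     as.integer(row * grid[2] + col))
  }
})

test_that("noiseless fitting yields degenerate windows at the exact angles", {
  cfg <- noiseless_config(duration_s = 60, seed = 13, walk_sd = 0,
                          walk_range = 0, p_watch_to_notwatch = 0,
                          p_exit = 0, initial_state = "watching")
  s <- simulate_session(cfg)
  lim <- fit_angular_limits(s)
  expect_s3_class(lim, "gw_limits")
  expect_lt(max(lim$yaw_hi - lim$yaw_lo), 1e-9)
  expect_lt(max(lim$pitch_hi - lim$pitch_lo), 1e-9)
  tgt <- s$faces[s$faces$true_identity == "target", ][1, ]
  exact <- face_screen_angles(tgt$x + tgt$w / 2, tgt$y + tgt$h / 2,
                              s$config$person_depth_m[1], s$config)
  expect_equal(lim$yaw_lo[1], exact$yaw, tolerance = 1e-9)
  expect_equal(lim$pitch_lo[1], exact$pitch, tolerance = 1e-9)
})

test_that("fitted window half-widths track the injected noise quantiles", {
  sigma <- 5
  cfg <- session_config(duration_s = 420, seed = 17, walk_sd = 0,
                        walk_range = 0, gaze_noise_deg = sigma,
                        p_watch_to_notwatch = 0, p_exit = 0, p_miss = 0,
                        initial_state = "watching", embedding_dim = 4,
                        fp_rate = 0)
  s <- simulate_session(cfg)
  lim <- fit_angular_limits(s, coverage_quantile = 0.9)
  fitted_cells <- lim[lim$n >= 1000, ]
  expect_gte(sum(fitted_cells$n), 5000)
  expected_half <- qnorm(0.95) * sigma
  expect_lt(abs((fitted_cells$yaw_hi[1] - fitted_cells$yaw_lo[1]) / 2 -
                  expected_half) / expected_half, 0.15)
  expect_lt(abs((fitted_cells$pitch_hi[1] - fitted_cells$pitch_lo[1]) / 2 -
                  expected_half) / expected_half, 0.15)
})

test_that("cells below min_samples inherit the global fallback window", {
  s <- cached_session("gaze_default",
                      session_config(duration_s = 120, seed = 19,
                                     p_watch_to_notwatch = 0.05,
                                     p_notwatch_to_watch = 0.05))
  lim <- fit_angular_limits(s, min_samples = 1e6)  # force fallback everywhere
  fb <- attr(lim, "fallback")
  expect_true(all(lim$yaw_lo == fb["yaw_lo"]))
  expect_true(all(lim$pitch_hi == fb["pitch_hi"]))
  expect_error(
    fit_angular_limits(simulate_session(
      noiseless_config(duration_s = 5, seed = 1, p_notwatch_to_watch = 0,
                       p_watch_to_notwatch = 0,
                       initial_state = "not_watching"))),
    class = "gazewatch_gaze_error")
})

test_that("gaze dichotomization is inclusive at boundaries and
           scale-invariant", {
  s <- cached_session("gaze_default",
                      session_config(duration_s = 120, seed = 19,
                                     p_watch_to_notwatch = 0.05,
                                     p_notwatch_to_watch = 0.05))
  lim <- fit_angular_limits(s)
  cell <- lim$cell[1]
  g <- attr(lim, "grid"); fsz <- attr(lim, "frame_size")
  row <- cell %/% g[2]; col <- cell %% g[2]
  cx <- (col + 0.5) * fsz[1] / g[2]; cy <- (row + 0.5) * fsz[2] / g[1]
  mid_pitch <- (lim$pitch_lo[1] + lim$pitch_hi[1]) / 2
  inside <- angles_to_gaze((lim$yaw_lo[1] + lim$yaw_hi[1]) / 2, mid_pitch)
  on_edge <- angles_to_gaze(lim$yaw_lo[1], mid_pitch)
  outside <- angles_to_gaze(lim$yaw_lo[1] - 1, mid_pitch)
  expect_true(classify_gaze(inside, cx, cy, lim))
  expect_true(classify_gaze(on_edge, cx, cy, lim))
  expect_false(classify_gaze(outside, cx, cy, lim))
  expect_identical(classify_gaze(inside * 7, cx, cy, lim),
                   classify_gaze(inside, cx, cy, lim))
  expect_error(classify_gaze(inside, cx, cy, lim, tv_position = "left"),
               class = "gazewatch_gaze_error")
})

test_that("widening the coverage quantile is monotone in sensitivity and
           specificity", {
  fam <- simulate_family(23, duration_s = 120)
  train <- simulate_session(session_config(duration_s = 240, seed = 123,
                                           p_watch_to_notwatch = 0.05,
                                           p_notwatch_to_watch = 0.05))
  s <- fam$session
  codes <- expand_gold(s$gold, s$n_frames)
  f <- s$faces[s$faces$true_identity == "target" &
                 codes[s$faces$frame_index + 1] %in%
                   c("watching", "not_watching"), ]
  truth <- codes[f$frame_index + 1] == "watching"
  res <- sapply(c(0.5, 0.8, 0.9, 0.99), function(cq) {
    lim <- fit_angular_limits(train, coverage_quantile = cq)
    pred <- classify_gaze(cbind(f$gx, f$gy, f$gz),
                          f$x + f$w / 2, f$y + f$h / 2, lim)
    cc <- confusion_counts(pred, truth)
    m <- metrics_from_counts(cc)
    c(sens = m$sensitivity, spec = m$specificity)
  })
  expect_true(all(diff(res["sens", ]) >= 0))
  expect_true(all(diff(res["spec", ]) <= 0))
})

test_that("leave-one-family-out recovers perfect accuracy on noiseless
           families and matches explicit refits", {
  # families share the same static seating, so the exact screen-direction
  # angles coincide across families and zero-noise recovery is exact
  seats <- cbind(c(150, 320, 490), c(160, 200, 180))
  sessions <- setNames(lapply(1:3, function(i)
    simulate_session(noiseless_config(duration_s = 40, seed = 30 + i,
                                      home_xy = seats, walk_sd = 0,
                                      walk_range = 0))),
    c("A", "B", "C"))
  res <- loo_evaluate(sessions)
  expect_equal(res$accuracy, rep(1, 3))
  # permuting the family order only permutes rows
  res_perm <- loo_evaluate(sessions[c(2, 3, 1)])
  expect_equal(dplyr::arrange(res, family),
               dplyr::arrange(res_perm, family))
  # held-out metrics equal an explicit refit for one fold
  lim_bc <- fit_angular_limits(sessions[c("B", "C")])
  sA <- sessions$A
  codes <- expand_gold(sA$gold, sA$n_frames)
  f <- sA$faces[sA$faces$true_identity == "target" &
                  codes[sA$faces$frame_index + 1] %in%
                    c("watching", "not_watching"), ]
  pred <- classify_gaze(cbind(f$gx, f$gy, f$gz), f$x + f$w / 2,
                        f$y + f$h / 2, lim_bc)
  cc <- confusion_counts(pred, codes[f$frame_index + 1] == "watching")
  expect_equal(res$accuracy[res$family == "A"],
               metrics_from_counts(cc)$accuracy)
})

test_that("a television position with a single family is skipped with a
           warning", {
  seats <- cbind(c(150, 320, 490), c(160, 200, 180))
  sessions <- list(
    a = simulate_session(noiseless_config(duration_s = 20, seed = 41,
                                          home_xy = seats,
                                          initial_state = "watching")),
    b = simulate_session(noiseless_config(duration_s = 20, seed = 42,
                                          home_xy = seats,
                                          initial_state = "watching")),
    c = simulate_session(noiseless_config(duration_s = 20, seed = 43,
                                          tv_position = "left")))
  expect_warning(res <- loo_evaluate(sessions), "single family")
  expect_identical(sort(res$family), c("a", "b"))
})

test_that("with moderate noise, held-out gaze accuracy beats the majority
           class by at least 10 points", {
  margins <- sapply(1:5, function(seed) {
    sessions <- setNames(lapply(1:3, function(i) simulate_session(
      session_config(duration_s = 90, seed = seed * 100 + i,
                     gaze_noise_deg = 10, embedding_dim = 8,
                     p_watch_to_notwatch = 0.05,
                     p_notwatch_to_watch = 0.05))), c("x", "y", "z"))
    res <- loo_evaluate(sessions)
    base <- sapply(sessions, function(s) {
      codes <- expand_gold(s$gold, s$n_frames)
      codes <- codes[codes %in% c("watching", "not_watching")]
      max(mean(codes == "watching"), mean(codes != "watching"))
    })
    mean(res$accuracy) - mean(base[res$family])
  })
  expect_gte(mean(margins), 0.10)
})
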