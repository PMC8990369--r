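# Agreement statistics: formula oracles, invariances, calibration.

test_that("confusion metrics apply the formulas exactly", {
  m <- metrics_from_counts(c(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  m2 <- metrics_from_counts(c(tp = 1, fn = 1, tn = 6, fp = 2))
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 0.75)
  expect_equal(m2$ppv, 1 / 3)
  expect_equal(m2$npv, 6 / 7)
  expect_equal(m2$fpr, 0.25)
  expect_equal(m2$accuracy, 0.7)
  m3 <- metrics_from_counts(c(tp = 3, fn = 1, tn = 0, fp = 0))
  expect_true(is.na(m3$specificity))
  expect_true(is.na(m3$fpr))
})

test_that("metrics agree with brute-force recounts of raw aligned series", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    pred <- runif(n) < runif(1)
    gold <- runif(n) < runif(1)
    cc <- confusion_counts(pred, gold)
    # brute force recount
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] && gold[j]) tp <- tp + 1
      else if (!pred[j] && !gold[j]) tn <- tn + 1
      else if (pred[j]) fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(unname(cc), c(tp, tn, fp, fn))
    m <- metrics_from_counts(cc)
    expect_equal(m$accuracy, (tp + tn) / n)
    # fpr = 1 - specificity whenever both defined
    if (!is.na(m$fpr)) expect_equal(m$fpr, 1 - m$specificity)
    # pabak against hand agreement count
    expect_equal(pabak(pred, gold), 2 * (tp + tn) / n - 1)
  }
})

test_that("pabak endpoints and confidence interval behave", {
  x <- runif(40) < 0.5
  expect_equal(pabak(x, x), 1)
  y <- x; y[1:20] <- !y[1:20]
  expect_equal(pabak(x, y), 0)
  p <- pabak(x, x, conf_level = 0.95)
  expect_equal(attr(p, "conf_low"), 1)  # Po = 1 has zero-width CI
  expect_error(pabak(logical(0), logical(0)),
               class = "gazewatch_stats_error")
})

test_that("pabak equals Cohen's kappa under balanced marginals", {
  # prevalence 0.5 for both raters, symmetric errors: no prevalence or
  # bias adjustment is needed, so the two statistics coincide
  pred <- rep(c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE), times = c(30, 10, 30, 10, 10, 10))
  gold <- rep(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), times = c(30, 10, 30, 10, 10, 10))
  expect_equal(mean(pred), 0.5)
  expect_equal(mean(gold), 0.5)
  expect_equal(pabak(pred, gold),
               cohen_kappa(ifelse(pred, "g", "n"), ifelse(gold, "g", "n")))
})

test_that("Cohen's kappa matches hand computation and nullity", {
  z <- c("watching", "not_watching", "watching", "cannot_tell")
  expect_equal(cohen_kappa(z, z), 1)
  # 2x2 toy table: coder1 = a,a,b,b ; coder2 = a,b,a,a
  c1 <- c("a", "a", "b", "b"); c2 <- c("a", "b", "a", "a")
  po <- mean(c1 == c2)
  pe <- (2 / 4) * (3 / 4) + (2 / 4) * (1 / 4)
  expect_equal(cohen_kappa(c1, c2), (po - pe) / (1 - pe))
  # cross-check against an established implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    tab <- table(c1, c2)
    expect_equal(cohen_kappa(c1, c2),
                 e1071::classAgreement(tab)$kappa)
  }
  # both coders constant and identical: chance agreement 1, undefined
  expect_true(is.na(cohen_kappa(rep("a", 5), rep("a", 5))))
  # independent uniform series: kappa centred on zero
  set.seed(72)
  ks <- replicate(200, {
    cohen_kappa(sample(letters[1:4], 60, TRUE), sample(letters[1:4], 60, TRUE))
  })
  expect_lt(abs(mean(ks)), 3 * sd(ks) / sqrt(length(ks)))
})

test_that("frame ICC hits its endpoints and the ANOVA mean-squares oracle", {
  fam <- rep(c("f1", "f2"), each = 10)
  x <- runif(20) < 0.5
  expect_equal(as.numeric(icc_frame(x, x, fam)), 1)
  expect_error(icc_frame(x, x, rep("f1", 20)),
               class = "gazewatch_stats_error")
  # oracle: two-way ANOVA mean squares via stats::aov
  set.seed(73)
  pred <- runif(20) < 0.6
  gold <- runif(20) < 0.4
  d <- data.frame(y = c(as.numeric(pred), as.numeric(gold)),
                  unit = factor(rep(1:20, 2)),
                  rater = factor(rep(1:2, each = 20)))
  ms <- anova(stats::aov(y ~ rater + unit, data = d))[["Mean Sq"]]
  msc <- ms[1]; msr <- ms[2]; mse <- ms[3]
  want <- (msr - mse) / (msr + mse + (2 / 20) * (msc - mse))
  expect_equal(as.numeric(icc_frame(pred, gold, fam)), want)
  # swapping raters leaves the ICC unchanged
  expect_equal(as.numeric(icc_frame(gold, pred, fam)),
               as.numeric(icc_frame(pred, gold, fam)))
})

test_that("frame ICC centres on zero for independent raters", {
  set.seed(74)
  fam <- rep(c("f1", "f2", "f3", "f4"), each = 25)
  vals <- replicate(200, {
    as.numeric(icc_frame(runif(100) < 0.5, runif(100) < 0.5, fam))
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("total-time ICC endpoints, contracts and parameter recovery", {
  tot <- c(10, 20, 30, 15)
  expect_equal(icc_total_time(tot, tot), 1)
  expect_error(icc_total_time(tot, c(10, 20, 0, 15)),
               class = "gazewatch_stats_error")
  expect_error(icc_total_time(1:2, 1:2), class = "gazewatch_stats_error")
  # one rater constant: no between-family variance shared
  v <- icc_total_time(rep(10, 4), c(9, 11, 10, 12))
  expect_lte(abs(v), 1)  # defined but near/below 0 per the variance contract
  expect_lt(v, 0.5)
  # recovery: log totals share variance rho of the between-family spread
  set.seed(75)
  rho <- 0.8; n <- 300
  u <- rnorm(n, 3, sqrt(rho))
  e1 <- rnorm(n, 0, sqrt(1 - rho)); e2 <- rnorm(n, 0, sqrt(1 - rho))
  est <- icc_total_time(exp(u + e1), exp(u + e2))
  expect_lt(abs(est - rho), 0.05)
  # rater swap invariance
  expect_equal(icc_total_time(exp(u + e1), exp(u + e2)),
               icc_total_time(exp(u + e2), exp(u + e1)))
})

test_that("ICC interpretation bands follow the stated cut-points", {
  expect_identical(classify_icc(0.725), "high")
  expect_identical(classify_icc(0.401), "moderate")
  expect_identical(classify_icc(0.35), "weak")
  expect_identical(classify_icc(0.9), "very_high")
  expect_identical(classify_icc(0.68), "high")
  expect_identical(classify_icc(-0.2), "weak")
})

test_that("paired Wilcoxon handles degenerate, shifted and null data", {
  v <- c(0.9, 0.8, 0.85, 0.95, 0.7)
  res <- wilcoxon_visits(v, v)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # five pairs all shifted by +1: the most extreme rank assignment;
  # enumerating the 2^5 sign assignments gives two-sided p = 2/32
  res2 <- wilcoxon_visits(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(res2$p_value, 2 / 32)
  expect_match(res2$method, "exact")
  # against R's exact distribution when there are no ties
  set.seed(42)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(wilcoxon_visits(a, b)$p_value,
               wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  expect_error(wilcoxon_visits(1:3, 2:4), class = "gazewatch_stats_error")
})

test_that("stratified summaries are descriptive, exact and permutation-safe", {
  tot <- tibble::tibble(est_minutes = c(10, 10, 20, 30),
                        gold_minutes = c(12, 12, 25, 28))
  g <- c("a", "a", "b", "b")
  s <- stratified_summary(tot, g)
  expect_equal(s$est_mean, c(10, 25))
  expect_equal(s$est_sd, c(0, sd(c(20, 30))))
  expect_equal(s$gold_mean, c(12, 26.5))
  # singleton group: undefined SD
  s2 <- stratified_summary(tot, c("a", "b", "b", "c"))
  expect_true(is.na(s2$est_sd[s2$group == "c"]))
  # permuting families permutes nothing but row contents
  perm <- c(3, 4, 1, 2)
  s3 <- stratified_summary(tot[perm, ], g[perm])
  expect_equal(s, s3)
  expect_error(stratified_summary(tot, c("a", "a", NA, "b")),
               class = "gazewatch_stats_error")
})

test_that("agreement reports drop cannot-tell frames and count
           out-of-frame as not watching", {
  codes <- c(rep("watching", 10), rep("not_watching", 5),
             rep("out_of_frame", 3), rep("cannot_tell", 2))
  gold <- encode_gold(codes)
  pred <- c(rep(TRUE, 10), rep(FALSE, 5), rep(TRUE, 3), rep(TRUE, 2))
  rep_ <- agreement_report(viewing_log(pred, 15), gold)
  expect_identical(rep_$n_used, 18L)
  expect_identical(rep_$n_dropped, 2L)
  # out_of_frame frames are gold-negative: the 3 TRUE predictions are FPs
  expect_identical(unname(rep_$counts),
                   c(10L, 5L, 3L, 0L))
  expect_equal(rep_$pabak, 2 * (15 / 18) - 1)
  expect_equal(glance(rep_)$pabak, rep_$pabak)
})

test_that("end-to-end total-time reliability is near-perfect at low noise
           and degrades but stays positive under dim light", {
  run_study <- function(lighting, gaze_noise, emb_noise, seed0) {
    purrr::map_dfr(1:10, function(i) {
      cc <- make_centroids(64, 3, 45, seed = seed0 + i + 50)
      enr <- simulate_session(session_config(
        duration_s = 15, seed = seed0 + i + 900, centroids = cc,
        embedding_dim = 64, embedding_noise_sd = emb_noise,
        gaze_noise_deg = gaze_noise,
        p_watch_to_notwatch = 0.05, p_notwatch_to_watch = 0.05))
      s <- simulate_session(session_config(
        duration_s = 120, seed = seed0 + i, centroids = cc,
        embedding_dim = 64, lighting = lighting,
        embedding_noise_sd = emb_noise, gaze_noise_deg = gaze_noise,
        p_watch_to_notwatch = 0.05, p_notwatch_to_watch = 0.05))
      lim <- fit_angular_limits(s)
      log <- run_pipeline(s, enroll_gallery(enr, 10), lim)
      tibble::tibble(
        est = total_viewing_time(log)$minutes,
        gold = total_viewing_time(gold_viewing_log(s))$minutes)
    })
  }
  low <- run_study("bright", gaze_noise = 2, emb_noise = 0.005, seed0 = 7000)
  keep <- low$est > 0 & low$gold > 0
  expect_gte(sum(keep), 8)
  expect_gt(icc_total_time(low$est[keep], low$gold[keep]), 0.9)

  dim_ <- run_study("dim", gaze_noise = 10, emb_noise = 0.016, seed0 = 8000)
  keep2 <- dim_$est > 0 & dim_$gold > 0
  expect_gt(icc_total_time(dim_$est[keep2], dim_$gold[keep2]), 0)
})
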