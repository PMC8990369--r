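# Agreement and performance statistics: confusion-matrix metrics, PABAK,
# Cohen's kappa, intraclass correlations (frame-level and total-time),
# paired Wilcoxon across visits, ICC interpretation bands and stratified
# summaries. Undefined metrics propagate as NA, never silently as 0.

#' Confusion counts from aligned binary series
#'
#' @param pred,truth Logical vectors of equal length (positive = gaze /
#'   target, depending on the stage).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  c(tp = sum(pred & truth), tn = sum(!pred & !truth),
    fp = sum(pred & !truth), fn = sum(!pred & truth))
}

#' Performance metrics from confusion counts
#'
#' Applies the standard formulas exactly: accuracy
#' (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' PPV TP/(TP+FP), NPV TN/(TN+FN), FPR FP/(FP+TN). Any zero denominator
#' yields `NA` (undefined).
#'
#' @param counts Named vector or list with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `fpr`.
#' @export
#' @examples
#' metrics_from_counts(c(tp = 1, fn = 1, tn = 6, fp = 2))
metrics_from_counts <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = rat(tp + tn, tp + tn + fp + fn),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn),
    fpr = rat(fp, fp + tn)
  )
}

#' Prevalence- and bias-adjusted kappa (PABAK)
#'
#' `PABAK = 2 * Po - 1`, where `Po` is the raw observed agreement between
#' the two binary series. Robust to skewed prevalence, which makes it the
#' agreement statistic of choice for frame-level viewing indicators where
#' most frames share one class.
#'
#' @param pred,gold Logical (or two-level) vectors of equal positive
#'   length, uncodable frames already removed.
#' @param conf_level If non-`NULL`, also return a large-sample CI obtained
#'   from the normal approximation to the agreement proportion
#'   (`2 * CI(Po) - 1`).
#' @return The PABAK value; with `conf_level`, attributes `conf_low` /
#'   `conf_high`.
#' @export
#' @examples
#' pabak(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))  # 1
pabak <- function(pred, gold, conf_level = NULL) {
  if (length(pred) == 0 || length(pred) != length(gold)) {
    abort("`pred` and `gold` must be equal-length, non-empty",
          class = "gazewatch_stats_error")
  }
  po <- mean(pred == gold)
  val <- 2 * po - 1
  if (!is.null(conf_level)) {
    z <- qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(po * (1 - po) / length(pred))
    attr(val, "conf_low") <- 2 * max(0, po - half) - 1
    attr(val, "conf_high") <- 2 * min(1, po + half) - 1
  }
  val
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` with the expected
#' agreement `Pe` from the product of the coders' marginal distributions;
#' supports any number of categories (e.g. the four duration codes used
#' for interrater reliability of gold logs).
#'
#' @param coder1,coder2 Equal-length categorical vectors.
#' @return Kappa in \[-1, 1\]; `NA` when `Pe = 1` (both coders constant
#'   and identical: chance correction undefined).
#' @export
cohen_kappa <- function(coder1, coder2) {
  if (length(coder1) == 0 || length(coder1) != length(coder2)) {
    abort("coder series must be equal-length, non-empty",
          class = "gazewatch_stats_error")
  }
  lv <- union(unique(coder1), unique(coder2))
  c1 <- factor(coder1, levels = lv); c2 <- factor(coder2, levels = lv)
  n <- length(c1)
  po <- mean(c1 == c2)
  pe <- sum((table(c1) / n) * (table(c2) / n))
  if (1 - pe < .Machine$double.eps) return(NA_real_)
  (po - pe) / (1 - pe)
}

# two-way absolute-agreement single-rater ICC (McGraw & Wong ICC(A,1))
# rows = units, exactly two raters
icc_a1 <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 2)
  x <- cbind(as.numeric(r1), as.numeric(r2))
  n <- nrow(x); k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(den) < .Machine$double.eps) return(NA_real_)
  (msr - mse) / den
}

#' Frame-level ICC between system and coder
#'
#' Two-rater absolute-agreement intraclass correlation of the per-frame
#' 0/1 viewing indicators, computed by two-way ANOVA variance
#' decomposition (McGraw & Wong ICC(A,1)) with frames treated as the
#' nested units of their families. This is a deterministic
#' linear-probability approximation of a binary-outcome mixed-model ICC;
#' the divergence is recorded in the `"estimator"` attribute.
#'
#' @param pred,gold Logical vectors (aligned frames, uncodable frames
#'   removed).
#' @param family Family id per frame; at least 2 distinct families are
#'   required.
#' @return ICC value with attributes `estimator` and `n_families`.
#' @export
icc_frame <- function(pred, gold, family) {
  if (length(unique(family)) < 2) {
    abort("frame-level ICC requires frames from at least 2 families",
          class = "gazewatch_stats_error")
  }
  stopifnot(length(pred) == length(gold), length(pred) == length(family))
  val <- icc_a1(pred, gold)
  structure(val,
            estimator = "ANOVA ICC(A,1) on 0/1 ratings (linear-probability approximation of a binary GLMM ICC); frames nested in families",
            n_families = length(unique(family)))
}

#' Total-viewing-time ICC across families
#'
#' Two-rater absolute-agreement ICC of the log-transformed per-family
#' total viewing times (system estimate vs gold standard), reflecting the
#' lognormal treatment of duration outcomes.
#'
#' @param est_minutes,gold_minutes Paired positive totals, one per family
#'   (n >= 3).
#' @return ICC value.
#' @export
icc_total_time <- function(est_minutes, gold_minutes) {
  if (length(est_minutes) != length(gold_minutes) || length(est_minutes) < 3) {
    abort("need paired totals for at least 3 families",
          class = "gazewatch_stats_error")
  }
  if (any(est_minutes <= 0) || any(gold_minutes <= 0)) {
    abort("totals must be positive for the log transform",
          class = "gazewatch_stats_error")
  }
  icc_a1(log(est_minutes), log(gold_minutes))
}

#' Interpretation band of an ICC
#'
#' Correlations of at most 0.35 are weak, 0.36 to 0.67 moderate, at least
#' 0.68 high, and at least 0.9 very high.
#'
#' @param value ICC in \[-1, 1\].
#' @return One of `"weak"`, `"moderate"`, `"high"`, `"very_high"`.
#' @export
#' @examples
#' classify_icc(0.725)  # high
#' classify_icc(0.401)  # moderate
classify_icc <- function(value) {
  stopifnot(value >= -1, value <= 1)
  if (value <= 0.35) "weak"
  else if (value < 0.68) "moderate"
  else if (value < 0.9) "high"
  else "very_high"
}

#' Paired Wilcoxon signed-rank test across visits
#'
#' Tests whether a per-family metric differs systematically between two
#' visits. Zero differences are discarded; for up to 25 remaining pairs
#' the exact two-sided p-value is computed from the signed-rank
#' distribution (full enumeration of sign assignments when there are 12 or
#' fewer pairs, which also handles tied absolute differences; the
#' standard exact distribution otherwise), and beyond that the normal
#' approximation with continuity and tie correction is used. If every
#' difference is zero the test is degenerate and p = 1 is reported with a
#' flag.
#'
#' @param visit1,visit2 Paired metric values (n >= 5 pairs).
#' @return Tibble: `statistic` (V, rank sum of positive differences),
#'   `p_value`, `n`, `n_nonzero`, `method`, `degenerate`.
#' @export
wilcoxon_visits <- function(visit1, visit2) {
  if (length(visit1) != length(visit2) || length(visit1) < 5) {
    abort("need at least 5 paired values", class = "gazewatch_stats_error")
  }
  d <- visit1 - visit2
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1,
                          n = length(d), n_nonzero = 0L,
                          method = "degenerate (all differences zero)",
                          degenerate = TRUE))
  }
  m <- length(nz)
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  ties <- any(duplicated(abs(nz)))
  if (m <= 12) {
    # enumerate all 2^m sign assignments of the observed |differences|
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    v_all <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
    method <- "exact (enumeration)"
  } else if (m <= 25 && !ties) {
    p <- suppressWarnings(
      wilcox.test(visit1, visit2, paired = TRUE, exact = TRUE)$p.value)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      wilcox.test(visit1, visit2, paired = TRUE, exact = FALSE,
                  correct = TRUE)$p.value)
    method <- "normal approximation with tie correction"
  }
  tibble::tibble(statistic = v_obs, p_value = p,
                 n = length(d), n_nonzero = m,
                 method = method, degenerate = FALSE)
}

#' Per-group summary of estimated and gold viewing time
#'
#' Group means and standard deviations of both totals (no inferential
#' tests: such stratified tables are descriptive). A singleton group's SD
#' is `NA` (undefined).
#'
#' @param totals Tibble with one row per family: columns `est_minutes`,
#'   `gold_minutes`.
#' @param group Group label per family (e.g. child race); every family
#'   must be labelled.
#' @return Tibble: `group`, `n`, `est_mean`, `est_sd`, `gold_mean`,
#'   `gold_sd`.
#' @export
stratified_summary <- function(totals, group) {
  if (length(group) != nrow(totals) || anyNA(group)) {
    abort("every family must carry a group label",
          class = "gazewatch_stats_error")
  }
  totals %>%
    dplyr::mutate(group = group) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(),
                     est_mean = mean(.data$est_minutes),
                     est_sd = if (dplyr::n() > 1) sd(.data$est_minutes) else NA_real_,
                     gold_mean = mean(.data$gold_minutes),
                     gold_sd = if (dplyr::n() > 1) sd(.data$gold_minutes) else NA_real_,
                     .groups = "drop")
}

#' Full agreement report of a viewing log against a gold log
#'
#' Aligns the pipeline's per-frame decisions with the duration-coded gold
#' log, drops frames coded `cannot_tell` from every statistic (a
#' measurement device still emits output there, but the frames are not
#' codable), treats `out_of_frame` as not watching (viewing requires
#' presence), and computes confusion metrics, PABAK (with large-sample
#' CI), binary Cohen's kappa and, when frames from several families are
#' supplied, the frame-level ICC.
#'
#' @param log A `gw_viewing_log` (or logical vector).
#' @param gold_log Duration-coded gold log tibble.
#' @param n_frames Frame count (defaults to the log length).
#' @param family Optional family id per frame (enables [icc_frame()]).
#' @return An object of class `"gw_agreement"`: list with `counts`,
#'   `metrics`, `pabak`, `pabak_ci`, `kappa`, `icc_frame`, `icc_band`,
#'   `n_used`, `n_dropped`, `estimator_note`.
#' @export
agreement_report <- function(log, gold_log, n_frames = NULL, family = NULL) {
  pred <- if (inherits(log, "gw_viewing_log")) log$viewing else as.logical(log)
  if (is.null(n_frames)) n_frames <- length(pred)
  codes <- expand_gold(gold_log, n_frames)
  keep <- codes != "cannot_tell"
  truth <- codes == "watching"           # out_of_frame counts as not watching
  pred_k <- pred[keep]; truth_k <- truth[keep]
  cc <- confusion_counts(pred_k, truth_k)
  pk <- pabak(pred_k, truth_k, conf_level = 0.95)
  icc_f <- NULL
  if (!is.null(family)) {
    fam_k <- family[keep]
    if (length(unique(fam_k)) >= 2) icc_f <- icc_frame(pred_k, truth_k, fam_k)
  }
  structure(
    list(counts = cc,
         metrics = metrics_from_counts(cc),
         pabak = as.numeric(pk),
         pabak_ci = c(low = attr(pk, "conf_low"), high = attr(pk, "conf_high")),
         kappa = cohen_kappa(ifelse(pred_k, "gaze", "no_gaze"),
                             ifelse(truth_k, "gaze", "no_gaze")),
         icc_frame = if (is.null(icc_f)) NA_real_ else as.numeric(icc_f),
         icc_band = if (is.null(icc_f)) NA_character_ else
           classify_icc(as.numeric(icc_f)),
         n_used = sum(keep), n_dropped = sum(!keep),
         estimator_note = if (is.null(icc_f)) NA_character_ else
           attr(icc_f, "estimator")),
    class = "gw_agreement")
}

#' @export
print.gw_agreement <- function(x, ...) {
  cat("<agreement report>\n")
  cat(sprintf("  frames used: %d (dropped %d cannot-tell)\n",
              x$n_used, x$n_dropped))
  m <- x$metrics
  cat(sprintf("  accuracy %.3f  sens %.3f  spec %.3f  ppv %.3f  npv %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv))
  cat(sprintf("  PABAK %.3f (95%% CI %.3f-%.3f)  kappa %.3f\n",
              x$pabak, x$pabak_ci["low"], x$pabak_ci["high"], x$kappa))
  if (!is.na(x$icc_frame)) {
    cat(sprintf("  frame ICC %.3f (%s)\n", x$icc_frame, x$icc_band))
  }
  invisible(x)
}
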