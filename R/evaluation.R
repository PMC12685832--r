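# Evaluation metrics and bootstrap statistics ---------------------------------

check_scored_set <- function(scores, labels, need_both = TRUE) {
  assert_that(length(scores) == length(labels) && length(scores) > 0,
              "scores and labels must be nonempty and of equal length")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  if (need_both) {
    assert_that(any(labels == 1) && any(labels == 0),
                "both classes must be present",
                class = "coopAS_single_class")
  }
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive is scored higher, ties
#' counted one half. Implemented via midranks, which is exactly equivalent.
#'
#' @param scores Numeric scores (any monotone scale).
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  check_scored_set(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: thresholds sweep the distinct score values
#' from high to low, and the area is the sum of precision at each threshold
#' weighted by the recall increment there (a right-continuous step
#' integral; no linear interpolation between operating points).
#'
#' @inheritParams roc_auc
#' @return AUPRC in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels) && length(scores) > 0,
              "scores and labels must be nonempty and of equal length")
  assert_that(any(labels == 1), "at least one positive is required",
              class = "coopAS_single_class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # group tied scores so each distinct value is one operating point
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  P <- sum(labels == 1)
  recall <- tp / P
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a threshold
#'
#' Positives are `score >= threshold`. Zero-denominator conventions:
#' precision is reported as 0 with `precision_undefined = TRUE` when nothing
#' is predicted positive; F1 is 0 when precision + recall is 0.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold.
#' @return List with `accuracy`, `precision`, `recall`, `specificity`, `f1`,
#'   `precision_undefined` and the confusion counts.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  check_scored_set(scores, labels, need_both = FALSE)
  assert_that(is.finite(threshold), "threshold must be finite")
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  prec_undef <- (tp + fp) == 0
  precision <- if (prec_undef) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(labels), precision = precision,
       recall = recall, specificity = specificity, f1 = f1,
       precision_undefined = prec_undef,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Select an operating threshold by Youden's J
#'
#' Scans every distinct score as a candidate threshold (positives =
#' `score >= t`) and returns the one maximizing J = recall + specificity - 1;
#' ties resolve to the lowest threshold.
#'
#' @inheritParams roc_auc
#' @return Numeric threshold.
#' @export
select_threshold <- function(scores, labels) {
  check_scored_set(scores, labels)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(t) {
    m <- threshold_metrics(scores, labels, t)
    m$recall + m$specificity - 1
  }, numeric(1))
  cand[which(j >= max(j) - 1e-12)[1]]
}

metric_fun <- function(metric, threshold = NULL) {
  if (is.function(metric)) return(metric)
  switch(metric,
         auroc = roc_auc,
         auprc = pr_auc,
         accuracy = function(s, l) threshold_metrics(s, l, threshold)$accuracy,
         precision = function(s, l) threshold_metrics(s, l, threshold)$precision,
         recall = function(s, l) threshold_metrics(s, l, threshold)$recall,
         specificity = function(s, l)
           threshold_metrics(s, l, threshold)$specificity,
         f1 = function(s, l) threshold_metrics(s, l, threshold)$f1,
         stop_coop("unknown metric: ", metric, class = "coopAS_invalid_input"))
}

#' Bootstrap a metric with percentile confidence interval
#'
#' Resamples the chosen unit (records, or whole patients to respect
#' within-patient clustering) with replacement, recomputes the metric per
#' replicate, and reports the bootstrap median with 2.5/97.5 percentile
#' bounds. Replicates on which the metric is undefined (e.g. a single-class
#' resample for AUROC) are dropped; more than 20% undefined is an error.
#'
#' @inheritParams roc_auc
#' @param metric Metric name (`"auroc"`, `"auprc"`, `"accuracy"`,
#'   `"precision"`, `"recall"`, `"specificity"`, `"f1"`) or a
#'   `function(scores, labels)`.
#' @param n Number of bootstrap replicates (>= 100; default 1000).
#' @param unit `"record"` or `"patient"` resampling.
#' @param patient_ids Required when `unit = "patient"`.
#' @param threshold Threshold for thresholded metrics.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Object of class `metric_report`: list with `metric`, `point`
#'   (bootstrap median), `ci_low`, `ci_high`, `n_bootstrap`, `n_dropped`.
#' @export
bootstrap_metric <- function(scores, labels, metric = "auroc", n = 1000L,
                             unit = c("record", "patient"),
                             patient_ids = NULL, threshold = NULL,
                             conf = 0.95, seed = NULL) {
  unit <- match.arg(unit)
  assert_that(n >= 100, "at least 100 bootstrap replicates are required")
  check_scored_set(scores, labels, need_both = FALSE)
  f <- metric_fun(metric, threshold)
  if (unit == "patient") {
    assert_that(!is.null(patient_ids) &&
                  length(patient_ids) == length(scores),
                "patient_ids must accompany patient-level resampling")
    groups <- split(seq_along(scores), patient_ids)
  }
  reps <- with_seed(seed, vapply(seq_len(n), function(i) {
    idx <- if (unit == "record") {
      sample.int(length(scores), replace = TRUE)
    } else {
      unlist(groups[sample.int(length(groups), replace = TRUE)],
             use.names = FALSE)
    }
    tryCatch(f(scores[idx], labels[idx]), error = function(e) NA_real_)
  }, numeric(1)))
  n_bad <- sum(is.na(reps))
  if (n_bad > 0.2 * n) {
    stop_coop("metric undefined on ", n_bad, " of ", n,
              " bootstrap replicates", class = "coopAS_bootstrap_error")
  }
  qs <- stats::quantile(reps, c((1 - conf) / 2, 0.5, (1 + conf) / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  structure(list(metric = if (is.character(metric)) metric else "custom",
                 point = qs[2], ci_low = qs[1], ci_high = qs[3],
                 n_bootstrap = n, n_dropped = n_bad),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("%s: %.3f (%.0f%% CI %.3f-%.3f; %d bootstrap replicates)\n",
              x$metric, x$point,
              100 * 0.95, x$ci_low, x$ci_high, x$n_bootstrap))
  invisible(x)
}

#' Paired bootstrap comparison of two models
#'
#' Both score vectors must be evaluated on the identical samples. Shared
#' resample indices give the bootstrap distribution of the metric
#' difference (model A minus model B); the CI is percentile-based and the
#' two-tailed p-value is `2 * min(P(diff <= 0), P(diff >= 0))` with add-one
#' smoothing, capped at 1.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared 0/1 labels.
#' @inheritParams bootstrap_metric
#' @return List with `difference` (point estimate on the full sample),
#'   `ci_low`, `ci_high`, `p_value`, `n_bootstrap`.
#' @export
compare_models <- function(scores_a, scores_b, labels, metric = "auroc",
                           n = 1000L, threshold = NULL, conf = 0.95,
                           seed = NULL) {
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "paired comparison requires scores on identical samples")
  f <- metric_fun(metric, threshold)
  point <- f(scores_a, labels) - f(scores_b, labels)
  diffs <- with_seed(seed, vapply(seq_len(n), function(i) {
    idx <- sample.int(length(labels), replace = TRUE)
    tryCatch(f(scores_a[idx], labels[idx]) - f(scores_b[idx], labels[idx]),
             error = function(e) NA_real_)
  }, numeric(1)))
  diffs <- diffs[!is.na(diffs)]
  nb <- length(diffs)
  assert_that(nb >= 0.8 * n, "metric undefined on too many replicates",
              class = "coopAS_bootstrap_error")
  qs <- stats::quantile(diffs, c((1 - conf) / 2, (1 + conf) / 2),
                        names = FALSE, type = 7)
  p <- 2 * min((sum(diffs <= 0) + 1) / (nb + 1),
               (sum(diffs >= 0) + 1) / (nb + 1))
  list(difference = point, ci_low = qs[1], ci_high = qs[2],
       p_value = min(p, 1), n_bootstrap = nb)
}
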