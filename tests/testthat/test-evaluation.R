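# brute-force oracles, kept independent of the implementations they check
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

ap_oracle <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  P <- sum(l); ap <- 0; prev_rec <- 0
  for (t in unique(s)) {
    keep <- s >= t
    tp <- sum(l[keep]); fp <- sum(keep) - tp
    rec <- tp / P
    ap <- ap + (rec - prev_rec) * tp / (tp + fp)
    prev_rec <- rec
  }
  ap
}

test_that("AUROC equals the Mann-Whitney pair statistic", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(1, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      scores <- sample(seq_len(8), n, replace = TRUE) / 8  # forces ties
      expect_identical(roc_auc(scores, labels), auc_pairs(scores, labels))
    }
    # complement symmetry in the absence of ties
    s <- rnorm(40); l <- c(0, 1, rbinom(38, 1, 0.5))
    expect_equal(roc_auc(s, l), 1 - roc_auc(-s, l))
  })
  expect_error(roc_auc(1:5, rep(1, 5)), class = "coopAS_single_class")
})

test_that("PR AUC follows the step-curve convention", {
  expect_equal(pr_auc(c(5, 4, 3, 1, 2), c(1, 1, 1, 0, 0)), 1.0)
  # a single positive ranked first among 10
  expect_equal(pr_auc(c(10, 9:1), c(1, rep(0, 9))), 1.0)
  withr::with_seed(2, {
    for (i in 1:30) {
      n <- sample(5:40, 1)
      labels <- c(1, rbinom(n - 1, 1, 0.3))
      scores <- sample(seq_len(6), n, replace = TRUE)
      expect_equal(pr_auc(scores, labels), ap_oracle(scores, labels))
    }
    # with random scores at large n the area approaches the prevalence
    s <- runif(10000); l <- rbinom(10000, 1, 0.2)
    expect_lt(abs(pr_auc(s, l) - 0.2), 0.02)
  })
})

test_that("threshold metrics match a hand-computed confusion matrix", {
  # TP=3 FP=1 FN=1 TN=5 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05, 0.02)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, 0.5)
  expect_equal(m[c("precision", "recall", "accuracy", "f1")],
               list(precision = 0.75, recall = 0.75, accuracy = 0.8,
                    f1 = 0.75))
  all_pos <- threshold_metrics(scores, labels, 0)
  expect_equal(all_pos$recall, 1)
  expect_equal(all_pos$specificity, 0)
  none <- threshold_metrics(scores, labels, 2)
  expect_equal(none$recall, 0)
  expect_equal(none$specificity, 1)
  expect_true(none$precision_undefined)
  expect_equal(none$precision, 0)
})

test_that("threshold selection maximizes Youden's J (exhaustive-scan oracle)", {
  withr::with_seed(3, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      scores <- round(rnorm(n, labels, 1.2), 2)
      thr <- select_threshold(scores, labels)
      j_at <- function(t) {
        m <- threshold_metrics(scores, labels, t)
        m$recall + m$specificity - 1
      }
      best_j <- max(vapply(unique(scores), j_at, numeric(1)))
      expect_equal(j_at(thr), best_j, tolerance = 1e-12)
    }
  })
  # perfectly separated classes: the returned threshold lies in the gap
  thr <- select_threshold(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_gt(thr, 3); expect_lte(thr, 7)
})

test_that("bootstrap metric reports seeded percentile intervals", {
  withr::with_seed(4, {
    scores <- rnorm(200, rbinom(200, 1, 0.3))
    labels <- as.numeric(scores + rnorm(200) > 0.5)
  })
  r1 <- bootstrap_metric(scores, labels, "auroc", n = 300, seed = 10)
  r2 <- bootstrap_metric(scores, labels, "auroc", n = 300, seed = 10)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$point)
  expect_gte(r1$ci_high, r1$point)
  # degenerate set: a single repeated pattern per class gives zero width
  d <- bootstrap_metric(c(rep(1, 30), rep(0, 30)),
                        c(rep(1, 30), rep(0, 30)), "auroc",
                        n = 200, seed = 1)
  expect_equal(d$ci_low, d$ci_high)
  # interval width shrinks with sample size
  withr::with_seed(5, {
    mk <- function(n) {
      y <- rbinom(n, 1, 0.3); s <- rnorm(n, y); list(s = s, y = y)
    }
    small <- mk(100); big <- mk(10000)
  })
  w <- function(x) x$ci_high - x$ci_low
  expect_lt(w(bootstrap_metric(big$s, big$y, "auroc", n = 200, seed = 2)),
            w(bootstrap_metric(small$s, small$y, "auroc", n = 200, seed = 2)))
  # patient-level resampling needs ids
  expect_error(bootstrap_metric(scores, labels, "auroc", n = 100,
                                unit = "patient"),
               class = "coopAS_invalid_input")
})

test_that("paired model comparison detects real differences and not null ones", {
  withr::with_seed(6, {
    y <- rbinom(500, 1, 0.3)
    good <- y + rnorm(500, 0, 0.6)
    noise <- rnorm(500)
  })
  null_cmp <- compare_models(good, good, y, "auroc", n = 400, seed = 1)
  expect_equal(null_cmp$difference, 0)
  expect_equal(null_cmp$p_value, 1)
  cmp <- compare_models(good, noise, y, "auroc", n = 400, seed = 2)
  expect_lt(cmp$p_value, 0.05)
  expect_gte(cmp$difference, cmp$ci_low - 0.05)
  expect_lte(cmp$difference, cmp$ci_high + 0.05)
  expect_error(compare_models(good, noise[1:10], y, "auroc"),
               class = "coopAS_invalid_input")
})
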