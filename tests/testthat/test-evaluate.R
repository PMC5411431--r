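test_that("AUC equals brute-force pairwise concordance", {
  brute_auc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  # worked micro-example: one concordant, one tied-free discordant pair
  expect_equal(auc_score(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(brute_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  withr::with_seed(19, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      labels <- rbinom(n, 1, 0.4)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), 2)   # rounding forces ties
      expect_equal(auc_score(scores, labels),
                   brute_auc(scores, labels))
    }
  })
  expect_error(auc_score(1:3, c(1, 1, 1)), "one class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(23, {
    labels <- rbinom(200, 1, 0.3)
    scores <- rnorm(200) + labels
  })
  base <- auc_score(scores, labels)
  expect_equal(auc_score(5 * scores - 2, labels), base)
  expect_equal(auc_score(exp(scores), labels), base)
  expect_equal(auc_score(plogis(scores), labels), base)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(29, {
    labels <- rbinom(300, 1, 0.3)
    scores <- rnorm(300) + 0.8 * labels
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
})

test_that("accuracy, precision, recall and F1 follow their definitions", {
  # TP=3 FP=1 FN=2 TN=4 at threshold 0.5
  posterior <- c(rep(0.9, 3), rep(0.1, 2), rep(0.8, 1), rep(0.2, 4))
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  r <- score_predictions(posterior, labels)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(r$accuracy, 0.7)
  # perfect predictions
  perf <- score_predictions(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$f1, 1)
  expect_equal(perf$auc, 1)
  # all-negative predictions: F1 falls back to 0, not NaN
  none <- score_predictions(c(0.1, 0.2), c(1, 0))
  expect_equal(none$f1, 0)
  # F1 equals the harmonic-mean closed form on random confusion tables
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- 40
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      posterior <- runif(n)
      if (length(unique(labels)) < 2) next
      r <- score_predictions(posterior, labels)
      tp <- sum(posterior >= 0.5 & labels == 1)
      fp <- sum(posterior >= 0.5 & labels == 0)
      fn <- sum(posterior < 0.5 & labels == 1)
      f1_brute <- if (2 * tp + fp + fn == 0) 0 else {
        2 * tp / (2 * tp + fp + fn)
      }
      expect_equal(r$f1, f1_brute)
    }
  })
})

test_that("per-subject breakdown scores each subject separately", {
  posterior <- c(0.9, 0.1, 0.8, 0.2)
  labels <- c(1, 0, 0, 1)
  r <- score_predictions(posterior, labels,
                         subjects = c("a", "a", "b", "b"))
  expect_equal(rownames(r$per_subject), c("a", "b"))
  expect_equal(r$per_subject["a", "accuracy"], 1)
  expect_equal(r$per_subject["b", "accuracy"], 0)
})

test_that("rank tables give rank 1 to the best value per metric", {
  vals <- rbind(best = c(3, 1), mid = c(2, 2), worst = c(1, 3))
  rt <- rank_classifiers(vals)
  expect_equal(unname(rt$avg_rank), c(2, 2, 2))
  # each column is a permutation of 1..K when there are no ties
  v2 <- matrix(c(0.9, 0.7, 0.8, 0.6, 0.75, 0.95), 3, 2)
  rt2 <- rank_classifiers(v2)
  for (j in 1:2) expect_setequal(rt2$ranks[, j], 1:3)
  # a classifier best on every metric has average rank 1
  v3 <- rbind(a = c(5, 5, 5), b = c(1, 2, 3), c = c(2, 1, 1))
  expect_equal(unname(rank_classifiers(v3)$avg_rank[1]), 1)
  # identical rows share mid-ranks
  v4 <- rbind(c(1, 1), c(1, 1))
  expect_equal(unname(rank_classifiers(v4)$avg_rank), c(1.5, 1.5))
  # cost-like metrics rank ascending
  v5 <- cbind(auc = c(0.9, 0.8), time = c(100, 50))
  rt5 <- rank_classifiers(v5, higher_is_better = c(TRUE, FALSE))
  expect_equal(unname(rt5$ranks[, "time"]), c(2, 1))
})

test_that("the Friedman statistic matches a brute-force evaluation", {
  brute <- function(R, K, N) {
    12 * N / (K * (K + 1)) * (sum(R^2) - K * (K + 1)^2 / 4)
  }
  # no differences: all average ranks equal (K+1)/2 -> statistic 0
  expect_equal(friedman_stat(rep(5, 9), n_metrics = 3)$chi2_f, 0)
  withr::with_seed(37, {
    for (rep in 1:1000) {
      K <- sample(3:10, 1)
      N <- sample(2:6, 1)
      ranks <- replicate(N, sample(K))
      R <- rowMeans(ranks)
      expect_equal(friedman_stat(R, n_metrics = N)$chi2_f,
                   brute(R, K, N), tolerance = 1e-12)
    }
  })
  # end to end from a metric matrix
  vals <- matrix(runif(12), 4, 3)
  rt <- rank_classifiers(vals)
  fr <- friedman_stat(rt)
  expect_equal(fr$df, 3)
  expect_equal(fr$chi2_f, brute(rt$avg_rank, 4, 3))
  fr2 <- friedman_stat(rt, critical = -1)
  expect_true(fr2$reject_null)
})
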