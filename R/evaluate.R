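#' Area under the ROC curve
#'
#' AUC is computed as the pairwise concordance probability: the fraction
#' of (positive, negative) pairs in which the positive trial receives the
#' higher score, ties counting one half. This equals the trapezoidal area
#' under the ROC curve and is invariant under any strictly monotone
#' transform of the scores.
#'
#' @param scores numeric scores (e.g. error posteriors), higher = more
#'   positive.
#' @param labels binary labels, 1 = positive (Error).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score a set of trial predictions
#'
#' Computes accuracy, precision, recall, F1 (harmonic mean of precision
#' and recall, 0 by convention when both are 0) and AUC, with Error as the
#' positive class. If `subjects` is given, a per-subject breakdown is
#' included.
#'
#' @param posterior numeric vector of error posteriors.
#' @param labels binary labels (1 = Error).
#' @param threshold decision threshold (boundary inclusive).
#' @param subjects optional subject id per trial for a per-subject table.
#' @return A list of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`, `n_trials` (and `per_subject`).
#' @export
score_predictions <- function(posterior, labels, threshold = 0.5,
                              subjects = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(posterior) == length(labels))
  pred <- as.integer(posterior >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  auc <- if (length(unique(labels)) < 2) {
    warning("AUC undefined: only one class present", call. = FALSE)
    NA_real_
  } else {
    auc_score(posterior, labels)
  }
  rep <- list(accuracy = mean(pred == labels), precision = precision,
              recall = recall, f1 = f1, auc = auc,
              n_trials = length(labels))
  if (!is.null(subjects)) {
    rep$per_subject <- do.call(rbind, lapply(
      split(seq_along(labels), subjects), function(i) {
        r <- suppressWarnings(
          score_predictions(posterior[i], labels[i], threshold))
        data.frame(accuracy = r$accuracy, f1 = r$f1, auc = r$auc,
                   n_trials = r$n_trials)
      }))
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Acc %.2f%%  F1 %.2f%%  AUC %s  (n = %d trials)\n",
    100 * x$accuracy, 100 * x$f1,
    if (is.na(x$auc)) "NA" else sprintf("%.2f%%", 100 * x$auc),
    x$n_trials))
  invisible(x)
}

#' Rank competing classifiers metric by metric
#'
#' Each metric column is ranked across the K classifiers (rank 1 = best;
#' ties get mid-ranks) and the per-classifier average rank R_j is taken
#' over the N metrics, as in nonparametric multi-classifier comparisons.
#'
#' @param values K x N numeric matrix, one row per classifier, one column
#'   per metric; row/column names are carried through.
#' @param higher_is_better logical, length 1 or N; `FALSE` for cost-like
#'   metrics such as computation time.
#' @return A list of class `rank_table` with `ranks` (K x N), `avg_rank`
#'   (length K), `K` and `N`.
#' @export
rank_classifiers <- function(values, higher_is_better = TRUE) {
  values <- as.matrix(values)
  hib <- rep_len(higher_is_better, ncol(values))
  ranks <- vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    rank(if (hib[j]) -v else v, ties.method = "average")
  }, numeric(nrow(values)))
  dimnames(ranks) <- dimnames(values)
  structure(list(ranks = ranks, avg_rank = rowMeans(ranks),
                 K = nrow(values), N = ncol(values)),
            class = "rank_table")
}

#' Friedman chi-square statistic from average ranks
#'
#' For K algorithms ranked over N conditions with average ranks R_j, the
#' Friedman statistic is
#' `chi2_F = 12 N / (K (K + 1)) * (sum_j R_j^2 - K (K + 1)^2 / 4)`,
#' distributed with K - 1 degrees of freedom under the null hypothesis
#' that all algorithms are equivalent (all R_j equal).
#'
#' @param avg_ranks either a `rank_table` from [rank_classifiers()] or a
#'   numeric vector of K average ranks.
#' @param n_metrics N, the number of ranked conditions (required when
#'   `avg_ranks` is a bare vector).
#' @param critical optional critical value; if supplied, the result
#'   carries a `reject_null` flag.
#' @return A list of class `friedman_result` with `chi2_f`, `df`, `K`,
#'   `N` and (optionally) `reject_null`.
#' @export
friedman_stat <- function(avg_ranks, n_metrics = NULL, critical = NULL) {
  if (inherits(avg_ranks, "rank_table")) {
    n_metrics <- avg_ranks$N
    avg_ranks <- avg_ranks$avg_rank
  }
  if (is.null(n_metrics)) {
    stop("`n_metrics` is required with a bare rank vector", call. = FALSE)
  }
  K <- length(avg_ranks)
  stopifnot(K >= 2, n_metrics >= 1)
  chi2 <- 12 * n_metrics / (K * (K + 1)) *
    (sum(avg_ranks^2) - K * (K + 1)^2 / 4)
  out <- list(chi2_f = chi2, df = K - 1L, K = K, N = n_metrics)
  if (!is.null(critical)) out$reject_null <- chi2 > critical
  class(out) <- "friedman_result"
  out
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2_F = %.4f on %d df (K = %d, N = %d)\n",
              x$chi2_f, x$df, x$K, x$N))
  if (!is.null(x$reject_null)) {
    cat(if (x$reject_null) "null rejected\n" else "null retained\n")
  }
  invisible(x)
}
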