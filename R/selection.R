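#' Cross-validated AUC of the ensemble decoder
#'
#' Stratified k-fold cross-validation of the full ensemble: for each fold
#' the ensemble is fitted on the remaining folds and its posterior scored
#' on the held-out fold; the mean of the per-fold validation AUCs is
#' returned. This is the objective driving electrode selection.
#'
#' @param X trials x features matrix.
#' @param y labels (1 = Error).
#' @param k number of folds (default 10).
#' @param seed integer seed; folds and all inner resampling derive from
#'   it, so the value is deterministic given `(X, y, k, seed)`.
#' @param resamples number of inner resamples (M = k of the inner plan)
#'   used when fitting the ensemble within each fold.
#' @param learners learners passed to [fit_ensemble()].
#' @param fold_aucs if `TRUE`, return the per-fold AUC vector instead of
#'   the mean.
#' @return Mean validation AUC (or per-fold vector).
#' @export
crossval_auc <- function(X, y, k = 10, seed = 1, resamples = k,
                         learners = c("lda", "qda", "lg_l1", "lg_l2"),
                         fold_aucs = FALSE) {
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("cannot stratify: a class has fewer than k = ", k,
         " observations", call. = FALSE)
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    plan <- build_resamples(y[tr], k = resamples, seed = seed + f)
    model <- fit_ensemble(X[tr, , drop = FALSE], y[tr], plan,
                          learners = learners)
    p <- ensemble_posterior(model, X[!tr, , drop = FALSE])
    auc_score(p, y[!tr])
  }, numeric(1))
  if (fold_aucs) aucs else mean(aucs)
}

# columns of X belonging to a channel subset plus the meta block
subset_columns <- function(feature_names, channels) {
  sig <- as.character(outer(paste0("_b", seq_len(N_BINS)),
                            intersect(montage_channels(), channels),
                            function(b, ch) paste0(ch, b)))
  c(match(sig, feature_names), which(feature_names %in% META_NAMES))
}

#' Greedy backward elimination of electrodes
#'
#' Starting from the full channel set, each electrode is examined once, in
#' montage order: the cross-validated AUC of the current subset without
#' that electrode is computed and, if it is at least the current reference
#' AUC, the electrode is permanently rejected and the reference updated;
#' otherwise the electrode is kept. Meta-features always stay in the
#' feature vector and are never candidates for removal. Ties favour the
#' smaller model (removal).
#'
#' @param X trials x features matrix whose signal columns are named
#'   `"<channel>_b<bin>"` (as produced by [featurize_recording()]).
#' @param y labels (1 = Error).
#' @param channels candidate channels (default: all channels present in
#'   `X`).
#' @param k folds for [crossval_auc()].
#' @param seed integer seed shared by every AUC evaluation, making the
#'   trace deterministic.
#' @param ... further arguments passed to [crossval_auc()].
#' @return A list of class `selection_trace`: `subset` (kept channels),
#'   `auc` (final reference AUC), `initial_auc` and `trace`, a data.frame
#'   with one row per examined channel (`channel`, `auc_with`,
#'   `auc_without`, `decision`).
#' @export
backward_eliminate <- function(X, y, channels = NULL, k = 10, seed = 1,
                               ...) {
  fn <- colnames(X)
  if (is.null(channels)) {
    channels <- intersect(montage_channels(),
                          unique(sub("_b[0-9]+$", "", fn)))
  }
  stopifnot(length(channels) >= 2)
  eval_auc <- function(chs) {
    crossval_auc(X[, subset_columns(fn, chs), drop = FALSE], y,
                 k = k, seed = seed, ...)
  }
  ref <- eval_auc(channels)
  initial <- ref
  kept <- channels
  trace <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    ch <- channels[i]
    cand <- setdiff(kept, ch)
    # an empty candidate set still carries the meta-features, so its AUC
    # is well defined; rejecting the last channel empties the subset and
    # triggers the fallback below
    auc_wo <- eval_auc(cand)
    if (auc_wo >= ref) {
      kept <- cand
      trace[[i]] <- data.frame(channel = ch, auc_with = ref,
                               auc_without = auc_wo,
                               decision = "rejected")
      ref <- auc_wo
    } else {
      trace[[i]] <- data.frame(channel = ch, auc_with = ref,
                               auc_without = auc_wo, decision = "kept")
    }
  }
  trace <- do.call(rbind, trace)
  if (length(kept) == 0) {
    warning("all channels rejected; falling back to the single best",
            call. = FALSE)
    singles <- vapply(channels, function(ch) eval_auc(ch), numeric(1))
    kept <- channels[which.max(singles)]
    ref <- max(singles)
  }
  structure(list(subset = kept, auc = ref, initial_auc = initial,
                 trace = trace),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "<selection_trace> kept %d of %d channels; AUC %.3f -> %.3f\n",
    length(x$subset), nrow(x$trace), x$initial_auc, x$auc))
  invisible(x)
}
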