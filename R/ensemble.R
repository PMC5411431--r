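#' Build the resampling plan for the ensemble
#'
#' The ensemble trains each learner on M resampled subsets of the training
#' data. Resamples are generated with the k-fold mechanism: the data are
#' split into k stratified folds and resample m is the training split of
#' fold m (so M = k and each resample holds (k-1)/k of the data, without
#' replacement). A bootstrap variant (`replace = TRUE`) draws the same
#' number of indices with replacement instead.
#'
#' @param y integer/logical label vector (1 = Error); stratification keeps
#'   both classes in every resample.
#' @param k number of folds (default 10); M = k resamples are produced.
#' @param seed integer seed; the plan is deterministic given `(y, k,
#'   seed)`.
#' @param replace draw with replacement instead of k-fold splits.
#' @return An object of class `resample_plan`: list with `indices` (list
#'   of M integer vectors), `folds` (fold id per observation), `M`, `k`,
#'   `seed`.
#' @export
build_resamples <- function(y, k = 10, seed = 1, replace = FALSE) {
  n <- length(y)
  stopifnot(n >= k, k >= 2)
  y <- as.integer(y)
  if (min(table(y)) < k) {
    stop("cannot stratify: a class has fewer than k = ", k,
         " observations", call. = FALSE)
  }
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    indices <- if (replace) {
      m <- round(n * (k - 1) / k)
      lapply(seq_len(k), function(i) sort(sample.int(n, m, replace = TRUE)))
    } else {
      lapply(seq_len(k), function(i) which(folds != i))
    }
  })
  structure(list(indices = indices, folds = folds, M = k, k = k,
                 seed = seed),
            class = "resample_plan")
}

# --- individual learners ------------------------------------------------
# Each fit_* returns a closure-free list with a matching predict_* giving
# P(Error = 1 | x) for the rows of a matrix.

fit_lda <- function(X, y, ridge = 1e-6) {
  cls <- sort(unique(y))
  stopifnot(length(cls) == 2)
  mu <- lapply(cls, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  n <- nrow(X)
  Sp <- 0
  for (i in seq_along(cls)) {
    Xi <- X[y == cls[i], , drop = FALSE]
    Sp <- Sp + crossprod(sweep(Xi, 2, mu[[i]]))
  }
  Sp <- Sp / (n - 2)
  d <- ncol(X)
  Sp <- Sp + diag(ridge * mean(diag(Sp)), d)
  R <- chol(Sp)
  prior <- as.numeric(table(factor(y, levels = cls))) / n
  list(type = "lda", classes = cls, mu = mu, R = R, prior = prior)
}

predict_lda <- function(fit, X) {
  # log posterior odds via the pooled-covariance discriminants
  scores <- vapply(seq_along(fit$classes), function(i) {
    z <- backsolve(fit$R, t(X) - fit$mu[[i]], transpose = TRUE)
    -0.5 * colSums(z^2) + log(fit$prior[i])
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  1 / (1 + exp(scores[, 1] - scores[, 2]))
}

fit_qda <- function(X, y, gamma = 0.07) {
  cls <- sort(unique(y))
  stopifnot(length(cls) == 2)
  d <- ncol(X)
  per_class <- lapply(cls, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- crossprod(sweep(Xi, 2, mu)) / (nrow(Xi) - 1)
    # covariance shrinkage toward a scaled identity
    S <- (1 - gamma) * S + diag(gamma * sum(diag(S)) / d, d)
    R <- tryCatch(chol(S), error = function(e) {
      warning("QDA covariance rank-deficient; adding ridge jitter",
              call. = FALSE)
      chol(S + diag(1e-8 * sum(diag(S)) / d, d))
    })
    list(mu = mu, R = R, logdet = 2 * sum(log(diag(R))))
  })
  prior <- as.numeric(table(factor(y, levels = cls))) / nrow(X)
  list(type = "qda", classes = cls, per_class = per_class, prior = prior)
}

predict_qda <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(i) {
    pc <- fit$per_class[[i]]
    z <- backsolve(pc$R, t(X) - pc$mu, transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * pc$logdet + log(fit$prior[i])
  }, numeric(nrow(X)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  1 / (1 + exp(scores[, 1] - scores[, 2]))
}

fit_logistic <- function(X, y, alpha, lambda = 0.15) {
  pad <- ncol(X) < 2            # glmnet requires >= 2 predictors
  if (pad) X <- cbind(X, 0)
  # decreasing lambda path ending at the target keeps glmnet's coordinate
  # descent warm-started and stable
  path <- exp(seq(log(lambda * 20), log(lambda), length.out = 8))
  fit <- glmnet::glmnet(X, factor(y, levels = sort(unique(y))),
                        family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE)
  list(type = if (alpha == 1) "lg_l1" else "lg_l2",
       fit = fit, lambda = lambda, pad = pad)
}

predict_logistic <- function(fit, X) {
  if (isTRUE(fit$pad)) X <- cbind(X, 0)
  as.numeric(stats::predict(fit$fit, X, s = fit$lambda,
                            type = "response"))
}

LEARNER_FITS <- list(
  lda = function(X, y, cfg) fit_lda(X, y, ridge = cfg$lda_ridge),
  qda = function(X, y, cfg) fit_qda(X, y, gamma = cfg$qda_gamma),
  lg_l1 = function(X, y, cfg) fit_logistic(X, y, 1, cfg$lg_lambda),
  lg_l2 = function(X, y, cfg) fit_logistic(X, y, 0, cfg$lg_lambda)
)

predict_learner <- function(fit, X) {
  switch(fit$type,
         lda = predict_lda(fit, X),
         qda = predict_qda(fit, X),
         lg_l1 = ,
         lg_l2 = predict_logistic(fit, X))
}

#' Fit the posterior-averaging ensemble decoder
#'
#' Trains the ensemble of four learners -- LDA, QDA with covariance
#' shrinkage gamma = 0.07, and logistic regression with an L1 and an L2
#' penalty of weight 0.15 -- on each of the M resamples of `plan`,
#' yielding L x M fitted estimators. Features are standardised (per-column
#' z-score) with statistics computed on the full training set; the scaler
#' is stored in the model and reapplied at prediction time.
#'
#' @param X trials x features numeric matrix.
#' @param y labels, 1 = Error / 0 = NoError; both classes must appear in
#'   every resample.
#' @param plan a [build_resamples()] plan (default: 10-fold plan with
#'   seed 1).
#' @param learners subset of `c("lda", "qda", "lg_l1", "lg_l2")`.
#' @param qda_gamma QDA covariance shrinkage weight.
#' @param lg_lambda logistic penalty weight (both norms).
#' @param lda_ridge relative ridge added to the pooled LDA covariance.
#' @param threshold posterior threshold used by [classify_trials()].
#' @return An object of class `errp_ensemble`.
#' @export
fit_ensemble <- function(X, y, plan = NULL,
                         learners = c("lda", "qda", "lg_l1", "lg_l2"),
                         qda_gamma = 0.07, lg_lambda = 0.15,
                         lda_ridge = 1e-6, threshold = 0.5) {
  stopifnot(is.matrix(X), nrow(X) == length(y), !anyNA(X))
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), length(unique(y)) == 2)
  if (is.null(plan)) plan <- build_resamples(y, k = 10, seed = 1)
  learners <- match.arg(learners, several.ok = TRUE)
  cfg <- list(qda_gamma = qda_gamma, lg_lambda = lg_lambda,
              lda_ridge = lda_ridge)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  fits <- lapply(learners, function(ln) {
    lapply(plan$indices, function(idx) {
      yi <- y[idx]
      if (length(unique(yi)) < 2) {
        stop("a resample lost a class; use a stratified plan",
             call. = FALSE)
      }
      LEARNER_FITS[[ln]](Xs[idx, , drop = FALSE], yi, cfg)
    })
  })
  names(fits) <- learners
  structure(list(fits = fits, learners = learners, M = plan$M,
                 center = center, scale = scale, threshold = threshold,
                 feature_names = colnames(X), config = cfg,
                 plan_seed = plan$seed),
            class = "errp_ensemble")
}

#' @export
print.errp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<errp_ensemble> %d learners x %d resamples = %d estimators, %d features\n",
    length(x$learners), x$M, length(x$learners) * x$M,
    length(x$center)))
  invisible(x)
}

#' Ensemble posterior probability of an error
#'
#' The decoder's output for a trial is the arithmetic mean of the L x M
#' per-estimator posterior probabilities of the Error class; averaging
#' proper posteriors keeps the result a proper probability and
#' `p(Error) + p(NoError) = 1` by construction.
#'
#' @param model an `errp_ensemble`.
#' @param X a feature vector or trials x features matrix on the model's
#'   feature layout.
#' @param per_learner if `TRUE`, also return the per-learner means.
#' @return Numeric vector of `p_error` in `[0, 1]` (or a list when
#'   `per_learner = TRUE`).
#' @export
ensemble_posterior <- function(model, X, per_learner = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$center)) {
    stop("feature dimensionality mismatch: got ", ncol(X),
         ", model expects ", length(model$center), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  by_learner <- lapply(model$fits, function(resample_fits) {
    ps <- vapply(resample_fits,
                 function(fit) predict_learner(fit, Xs),
                 numeric(nrow(Xs)))
    if (is.null(dim(ps))) ps <- matrix(ps, nrow = nrow(Xs))
    rowMeans(ps)
  })
  p <- Reduce(`+`, by_learner) / length(by_learner)
  p <- pmin(pmax(p, 0), 1)
  if (per_learner) list(p_error = p, per_learner = by_learner) else p
}

#' Threshold posteriors into hard labels
#'
#' @param p_error numeric vector of ensemble posteriors.
#' @param threshold decision threshold in (0, 1); the boundary is
#'   inclusive, `p_error >= threshold` yields `"Error"`.
#' @return Character vector in `{"Error", "NoError"}`.
#' @export
classify_trials <- function(p_error, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  ifelse(p_error >= threshold, "Error", "NoError")
}
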