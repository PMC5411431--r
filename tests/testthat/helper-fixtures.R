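# Shared fixtures, all generated in code.

# Two Gaussian clouds separated along every tenth feature.
make_clouds <- function(n = 100, d = 20, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(rnorm(n * d), n, d)
    X[y == 1L, seq(1, d, by = 10)] <-
      X[y == 1L, seq(1, d, by = 10)] + sep
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y)
  })
}

# Feature matrix with the package's channel-block column layout:
# `channels` blocks of 8 + the 9 meta columns. Only `informative`
# channels carry class signal.
make_channel_features <- function(n = 120, channels = paste0("ch", 1:4),
                                  informative = channels[1], sep = 3,
                                  seed = 1) {
  channels <- intersect(montage_channels(), channels)
  stopifnot(length(channels) >= 1)
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    cols <- list()
    for (ch in channels) {
      blk <- matrix(rnorm(n * 8), n, 8)
      if (ch %in% informative) {
        blk[y == 1L, c(2, 3)] <- blk[y == 1L, c(2, 3)] + sep
      }
      colnames(blk) <- paste0(ch, "_b", 1:8)
      cols[[ch]] <- blk
    }
    meta <- matrix(rnorm(n * 9), n, 9)
    colnames(meta) <- c("meta_mean", "meta_variance", "meta_session",
                        "meta_feedback", "meta_alphabet", "meta_word",
                        "meta_total_feedback", "meta_total_word",
                        "meta_sequence")
    X <- do.call(cbind, c(unname(cols), list(meta)))
    list(X = X, y = y, channels = channels)
  })
}

# A short raw recording (n_trials feedback events) plus its plan.
# Balanced error rates keep both classes present in tiny fixtures.
make_short_recording <- function(n_trials = 10, seed = 5,
                                 profile = subject_profile(
                                   "01", error_rate_fast = 0.5,
                                   error_rate_slow = 0.5)) {
  plan <- make_session_plan(profile, 1, seed = seed)[seq_len(n_trials), ]
  rec <- synthesize_recording(plan, profile, seed = seed + 1)
  list(plan = plan, rec = rec, profile = profile)
}

# A tiny ensemble trained on a short recording, for decoder tests.
make_tiny_model <- function(fixture, channels = montage_channels()) {
  pp <- preprocess_recording(fixture$rec, apply_ica = FALSE)
  fz <- featurize_recording(pp$recording, fixture$plan, channels)
  plan <- build_resamples(fz$y, k = 2, seed = 3)
  suppressWarnings(fit_ensemble(fz$X, fz$y, plan))
}
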