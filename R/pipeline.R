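#' Offline preprocessing of a continuous recording
#'
#' The batch path of the decoder's front end: causal elliptic band-pass
#' (0.1-10 Hz), optional ICA-based ocular artifact removal, then
#' Savitzky-Golay smoothing of every scalp channel. Filtering is
#' forward-only so the offline and streaming paths share one code path.
#'
#' @param rec a raw `errp_recording`.
#' @param filt band-pass design (default [design_bandpass()]).
#' @param kernel smoothing kernel (default [sg_kernel()]).
#' @param apply_ica run [remove_eog()] (default `TRUE`; requires >= 60 s
#'   of data).
#' @param ica_seed seed for the ICA unmixing.
#' @param ... further arguments to [remove_eog()].
#' @return A list: `recording` (preprocessed) and `ica_report` (`NULL`
#'   when ICA is skipped).
#' @export
preprocess_recording <- function(rec, filt = design_bandpass(),
                                 kernel = sg_kernel(),
                                 apply_ica = TRUE, ica_seed = 1, ...) {
  out <- apply_bandpass(rec, filt)
  report <- NULL
  if (apply_ica) {
    cleaned <- remove_eog(out, seed = ica_seed, ...)
    out <- cleaned$recording
    report <- cleaned$report
  }
  scalp <- which(out$channel_names != "EOG")
  for (i in scalp) {
    out$samples[i, ] <- sg_smooth(out$samples[i, ], kernel)
  }
  list(recording = out, ica_report = report)
}

#' Batch decoding of a full recording
#'
#' The offline counterpart of [stream_decode()]: preprocesses the whole
#' recording at once (band-pass + smoothing; ICA optional), featurizes
#' every feedback event and applies the trained ensemble.
#'
#' @inheritParams stream_decode
#' @param apply_ica run ICA cleaning before smoothing (default `FALSE`,
#'   matching the streaming path, which has no ICA stage).
#' @param ica_seed seed for ICA when enabled.
#' @return A data.frame with `id`, `posterior_error`, `label`.
#' @export
decode_batch <- function(rec, model, plan,
                         channels = montage_channels(),
                         filt = design_bandpass(),
                         kernel = sg_kernel(), apply_ica = FALSE,
                         ica_seed = 1) {
  pp <- preprocess_recording(rec, filt, kernel, apply_ica = apply_ica,
                             ica_seed = ica_seed)
  fz <- featurize_recording(pp$recording, plan, channels)
  p <- ensemble_posterior(model, fz$X)
  data.frame(id = fz$ids, posterior_error = p,
             label = classify_trials(p, model$threshold),
             stringsAsFactors = FALSE)
}

#' Featurize a synthetic corpus
#'
#' Preprocesses and featurizes every session of every subject of a
#' [generate_corpus()] result, stacking the per-trial feature vectors.
#'
#' @param corpus output of [generate_corpus()] (with recordings).
#' @param channels electrode subset.
#' @param apply_ica run per-session ICA cleaning (default `TRUE`).
#' @param filt,kernel preprocessing parameters.
#' @param seed base seed for the per-session ICA initialisations.
#' @return A list: `X` (trials x features), `y` (1 = Error), `ids`,
#'   `subject` (subject id per trial).
#' @export
corpus_features <- function(corpus, channels = montage_channels(),
                            apply_ica = TRUE,
                            filt = design_bandpass(),
                            kernel = sg_kernel(), seed = 1) {
  parts <- list()
  for (s in seq_along(corpus)) {
    for (sess in corpus[[s]]$sessions) {
      pp <- preprocess_recording(sess$recording, filt, kernel,
                                 apply_ica = apply_ica,
                                 ica_seed = seed + 977L * s +
                                   sess$plan$session[1])
      fz <- featurize_recording(pp$recording, sess$plan, channels)
      fz$subject <- rep(corpus[[s]]$profile$subject_id, nrow(fz$X))
      parts[[length(parts) + 1L]] <- fz
    }
  }
  list(X = do.call(rbind, lapply(parts, `[[`, "X")),
       y = unlist(lapply(parts, `[[`, "y")),
       ids = unlist(lapply(parts, `[[`, "ids")),
       subject = unlist(lapply(parts, `[[`, "subject")))
}

#' Cross-subject transfer experiment at desk scale
#'
#' The package's end-to-end check of the transferable-decoder property:
#' synthesize `n_train + n_test` subjects, fit the ensemble on the
#' training subjects only, and score its posteriors on the held-out
#' subjects, which the model has never seen. With the generator's default
#' high-SNR profile the held-out AUC should be well above chance; with
#' `errp_gain = 0` the labels are independent of the signal and the AUC
#' must sit at chance level.
#'
#' @param n_train,n_test numbers of training and held-out subjects.
#' @param seed master seed controlling synthesis, resampling and ICA.
#' @param profile optional fixed [subject_profile()] for all subjects.
#' @param k resampling folds of the ensemble plan.
#' @param apply_ica run per-session ICA cleaning.
#' @param channels electrode subset.
#' @return A list: `auc` (held-out AUC), `metrics` (full
#'   `metrics_report` on the held-out subjects), `model`, `n_train_trials`,
#'   `n_test_trials`.
#' @export
transfer_experiment <- function(n_train = 4, n_test = 2, seed = 1,
                                profile = NULL, k = 10,
                                apply_ica = TRUE,
                                channels = montage_channels()) {
  corpus <- generate_corpus(n_train + n_test, seed = seed,
                            profile = profile)
  feats <- corpus_features(corpus, channels, apply_ica = apply_ica,
                           seed = seed + 17L)
  train_ids <- sprintf("%02d", seq_len(n_train))
  tr <- feats$subject %in% train_ids
  plan <- build_resamples(feats$y[tr], k = k, seed = seed + 101L)
  model <- fit_ensemble(feats$X[tr, , drop = FALSE], feats$y[tr], plan)
  p <- ensemble_posterior(model, feats$X[!tr, , drop = FALSE])
  metrics <- score_predictions(p, feats$y[!tr],
                               subjects = feats$subject[!tr])
  list(auc = metrics$auc, metrics = metrics, model = model,
       n_train_trials = sum(tr), n_test_trials = sum(!tr))
}
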