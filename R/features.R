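EPOCH_PRE <- 40L    # samples before feedback onset (200 ms at 200 Hz)
EPOCH_POST <- 200L  # samples from onset onward (1000 ms)
N_BINS <- 8L        # downsampled features per channel
META_NAMES <- c("meta_mean", "meta_variance", "meta_session",
                "meta_feedback", "meta_alphabet", "meta_word",
                "meta_total_feedback", "meta_total_word",
                "meta_sequence")

#' Extract a feedback-locked epoch
#'
#' Cuts the window from 200 ms before to 1000 ms after a feedback onset
#' (240 samples per channel at 200 Hz: 40 pre + 200 post). If the onset
#' falls within the first 200 ms of the recording, the missing pre-onset
#' samples are mirror-padded (the cold-start rule of the streaming path).
#'
#' @param rec an `errp_recording` (typically band-passed, cleaned and
#'   smoothed).
#' @param onset_sample 1-based sample index of the feedback onset.
#' @param channels channel names to include (default: the 56 scalp
#'   channels).
#' @return channels x 240 numeric matrix with channel rownames.
#' @export
extract_epoch <- function(rec, onset_sample,
                          channels = montage_channels()) {
  o <- as.integer(onset_sample)
  if (o + EPOCH_POST - 1L > ncol(rec$samples)) {
    stop("onset at sample ", o, " runs past the end of the recording",
         call. = FALSE)
  }
  rows <- match(channels, rec$channel_names)
  if (anyNA(rows)) {
    stop("channel not in recording: ", channels[is.na(rows)][1],
         call. = FALSE)
  }
  idx <- (o - EPOCH_PRE):(o + EPOCH_POST - 1L)
  if (idx[1] < 1L) {
    n_pad <- 1L - idx[1]
    idx <- c((n_pad + 1L):2L, idx[idx >= 1L])  # mirror about sample 1
  }
  ep <- rec$samples[rows, idx, drop = FALSE]
  rownames(ep) <- channels
  ep
}

#' Baseline-correct an epoch
#'
#' Subtracts, per channel, the mean over the 200 ms pre-onset segment
#' (the first 40 samples) from the whole epoch, removing slow background
#' offset so that post-onset deflections are measured against the
#' pre-feedback level.
#'
#' @param epoch channels x 240 matrix from [extract_epoch()].
#' @return Matrix of the same shape; the mean of each channel's first 40
#'   samples is exactly zero afterwards.
#' @export
baseline_correct <- function(epoch) {
  stopifnot(ncol(epoch) == EPOCH_PRE + EPOCH_POST)
  base <- rowMeans(epoch[, seq_len(EPOCH_PRE), drop = FALSE])
  epoch - base
}

#' Downsample an epoch to 8 features per channel
#'
#' The 200 post-onset samples are partitioned into 8 contiguous bins of
#' 25 samples (125 ms) and each feature is the bin mean. Pre-onset samples
#' are used only for baseline correction, never featurized. The reduction
#' keeps the classifier input small (8 values per electrode) while
#' averaging out sample-level noise.
#'
#' @param epoch baseline-corrected channels x 240 matrix.
#' @return channels x 8 matrix of bin means.
#' @export
downsample_epoch <- function(epoch) {
  stopifnot(ncol(epoch) == EPOCH_PRE + EPOCH_POST)
  post <- epoch[, (EPOCH_PRE + 1L):(EPOCH_PRE + EPOCH_POST),
                drop = FALSE]
  bin <- rep(seq_len(N_BINS), each = EPOCH_POST / N_BINS)
  out <- t(apply(post, 1, function(row) tapply(row, bin, mean)))
  dimnames(out) <- list(rownames(epoch), paste0("b", seq_len(N_BINS)))
  out
}

#' Compute the 9 experiment meta-features
#'
#' In addition to the waveform features, each trial carries 9 scalars: the
#' grand mean and grand (population) variance of the baseline-corrected
#' epoch over all channels and samples, plus 7 counters describing where
#' the trial sits in the experiment (session, feedback number within the
#' session, alphabet position, word number, cumulative feedback and word
#' counts since session 1, and the flashing condition, long = 1 /
#' short = 0).
#'
#' @param meta one row of a session plan ([make_session_plan()]).
#' @param epoch baseline-corrected channels x 240 matrix.
#' @return Named numeric vector of length 9.
#' @export
compute_meta <- function(meta, epoch) {
  v <- as.numeric(epoch)
  stats::setNames(
    c(mean(v), mean((v - mean(v))^2),
      meta$session, meta$feedback_index, meta$letter_position,
      meta$word_index, meta$total_feedback, meta$total_word,
      meta$sequence_type),
    META_NAMES)
}

#' Assemble the trial feature vector
#'
#' Concatenates the 8-value signal block of every selected channel, in
#' montage order, followed by the 9 meta-features: length
#' `8 * n_channels + 9` (457 for the full 56-channel montage).
#'
#' @param signal_features channels x 8 matrix from [downsample_epoch()]
#'   with channel rownames.
#' @param meta_features length-9 vector from [compute_meta()].
#' @param channels channel subset to keep (montage order is enforced).
#' @return Named numeric vector; signal entries are named
#'   `"<channel>_b<bin>"`.
#' @export
assemble_features <- function(signal_features, meta_features,
                              channels = rownames(signal_features)) {
  channels <- intersect(montage_channels(), channels)  # montage order
  missing <- setdiff(channels, rownames(signal_features))
  if (length(missing)) {
    stop("no signal features for channel: ", missing[1], call. = FALSE)
  }
  blocks <- t(signal_features[channels, , drop = FALSE])
  sig <- as.numeric(blocks)
  names(sig) <- as.character(outer(paste0("_b", seq_len(N_BINS)),
                                   channels,
                                   function(b, ch) paste0(ch, b)))
  c(sig, meta_features)
}

#' Featurize every trial of a session
#'
#' Runs epoch extraction, baseline correction, downsampling and
#' meta-feature computation for each feedback event of a preprocessed
#' recording, returning the stacked feature matrix.
#'
#' @param rec a preprocessed (band-passed, cleaned, smoothed)
#'   `errp_recording`.
#' @param plan the session plan matching the recording.
#' @param channels channel subset (default all 56).
#' @return A list: `X` (trials x features matrix), `y` (integer labels,
#'   1 = Error, `NA` if the plan has no labels), `ids` (feedback ids).
#' @export
featurize_recording <- function(rec, plan,
                                channels = montage_channels()) {
  onsets <- which(rec$feedback_marker == 1L)
  if (length(onsets) != nrow(plan)) {
    stop("marker count (", length(onsets),
         ") does not match plan rows (", nrow(plan), ")", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    ep <- baseline_correct(extract_epoch(rec, onsets[i], channels))
    assemble_features(downsample_epoch(ep),
                      compute_meta(plan[i, ], ep), channels)
  })
  X <- do.call(rbind, rows)
  list(X = X,
       y = if ("is_error" %in% names(plan)) {
         as.integer(plan$is_error)
       } else {
         rep(NA_integer_, nrow(plan))
       },
       ids = feedback_id(plan$subject_id, plan$session,
                         plan$feedback_index))
}
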