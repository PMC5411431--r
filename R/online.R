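SG_HALF <- 15L       # smoothing half-window in samples (75 ms)
CARRY_OVER <- 20L    # history prepended to each block (100 ms)

#' Pseudo-online streaming decoding
#'
#' Replays a continuous recording through the online path of the decoder:
#' samples arrive in chunks, are band-pass filtered causally with carried
#' filter state, and a feedback switch watches the marker track. When a
#' feedback onset is seen, the decoder cuts the block from 200 ms before
#' to 1000 ms after the onset, prepends 100 ms of already-seen history so
#' the smoothing window of the first epoch samples is fully covered,
#' applies Savitzky-Golay smoothing, baseline-corrects, downsamples,
#' merges the trial meta-features, and emits the ensemble posterior and
#' hard label. Non-feedback samples are discarded once the buffer no
#' longer needs them, so memory use is independent of stream length.
#'
#' A prediction is emitted as soon as the epoch plus the smoothing
#' half-window (75 ms) beyond its end has arrived; apart from a cold-start
#' first trial (mirror-padded, flagged in the log), the posteriors are
#' identical to batch decoding of the same recording.
#'
#' @param rec the raw `errp_recording` to stream (marker track included).
#' @param model a fitted `errp_ensemble`.
#' @param plan session plan supplying the meta-features, one row per
#'   marker event in order.
#' @param channels electrode subset selected at training time.
#' @param filt band-pass design (default [design_bandpass()]).
#' @param kernel smoothing kernel (default [sg_kernel()]).
#' @param chunk_s chunk duration in seconds for the simulated stream.
#' @return A data.frame with one row per feedback event: `id`,
#'   `posterior_error`, `label`, `computation_time` (microseconds),
#'   `cold_start`.
#' @export
stream_decode <- function(rec, model, plan,
                          channels = montage_channels(),
                          filt = design_bandpass(),
                          kernel = sg_kernel(), chunk_s = 0.25) {
  stopifnot(inherits(rec, "errp_recording"),
            inherits(model, "errp_ensemble"))
  rows <- match(channels, rec$channel_names)
  if (anyNA(rows)) {
    stop("channel not in recording: ", channels[is.na(rows)][1],
         call. = FALSE)
  }
  fs <- rec$sampling_rate
  n_total <- ncol(rec$samples)
  chunk <- max(1L, round(chunk_s * fs))
  n_ch <- length(rows)
  zi <- lapply(seq_len(n_ch), function(i) {
    matrix(0, nrow = nrow(filt$sos), ncol = 2)
  })
  need_left <- EPOCH_PRE + CARRY_OVER
  need_right <- EPOCH_POST - 1L + SG_HALF
  capacity <- need_left + need_right + chunk + 1L

  buf <- matrix(numeric(0), nrow = n_ch, ncol = 0)
  buf_start <- 1L   # absolute index of buf[, 1]
  pending <- integer(0)
  n_seen <- 0L
  event_no <- 0L
  out <- vector("list", sum(rec$feedback_marker))

  pos <- 1L
  while (pos <= n_total) {
    hi <- min(pos + chunk - 1L, n_total)
    raw <- rec$samples[rows, pos:hi, drop = FALSE]
    filt_chunk <- matrix(0, nrow = n_ch, ncol = ncol(raw))
    for (i in seq_len(n_ch)) {
      st <- filter_signal(raw[i, ], filt, zi[[i]])
      filt_chunk[i, ] <- st$y
      zi[[i]] <- st$zi
    }
    buf <- cbind(buf, filt_chunk)
    n_seen <- hi
    pending <- c(pending,
                 pos - 1L + which(rec$feedback_marker[pos:hi] == 1L))

    ready <- pending[pending + need_right <= n_seen]
    for (onset in ready) {
      t_start <- Sys.time()
      lo <- onset - need_left
      cold <- lo < 1L
      b_lo <- max(lo, buf_start)
      block <- buf[, (b_lo - buf_start + 1L):(onset + need_right -
                                                buf_start + 1L),
                   drop = FALSE]
      if (cold && b_lo > lo) {
        n_pad <- b_lo - lo
        block <- cbind(block[, (n_pad + 1L):2L, drop = FALSE], block)
      }
      sm <- t(apply(block, 1, sg_smooth, kernel = kernel))
      e_from <- (onset - EPOCH_PRE) - lo + 1L
      ep <- sm[, e_from:(e_from + EPOCH_PRE + EPOCH_POST - 1L),
               drop = FALSE]
      rownames(ep) <- channels
      ep <- baseline_correct(ep)
      event_no <- event_no + 1L
      meta <- plan[event_no, ]
      x <- assemble_features(downsample_epoch(ep),
                             compute_meta(meta, ep), channels)
      p <- ensemble_posterior(model, x)
      dt_us <- max(1, as.numeric(Sys.time() - t_start, units = "secs") *
                     1e6)
      out[[event_no]] <- data.frame(
        id = feedback_id(meta$subject_id, meta$session,
                         meta$feedback_index),
        posterior_error = p,
        label = classify_trials(p, model$threshold),
        computation_time = dt_us,
        cold_start = cold,
        stringsAsFactors = FALSE)
    }
    pending <- setdiff(pending, ready)
    # discard samples no one still needs
    keep_from <- n_seen - capacity + 1L
    if (length(pending)) {
      keep_from <- min(keep_from, min(pending) - need_left)
    }
    keep_from <- max(keep_from, 1L)
    if (keep_from > buf_start) {
      buf <- buf[, (keep_from - buf_start + 1L):ncol(buf),
                 drop = FALSE]
      buf_start <- keep_from
    }
    pos <- hi + 1L
  }
  do.call(rbind, out)
}
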