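#' @section Session design:
#' Each simulated subject performs five copy-spelling sessions. Sessions 1-4
#' contain 12 five-letter words (60 feedback periods each); session 5
#' contains 20 five-letter words (100 feedback periods). A full subject
#' therefore contributes 4 x 60 + 100 = 340 feedback-locked trials. Words
#' are spelled under one of two flashing conditions: a fast, more
#' error-prone condition ("short" sequences, coded 0) and a slower, less
#' error-prone one ("long" sequences, coded 1).
#' @name session-design
#' @keywords internal
NULL

FS_HZ <- 200
TRIAL_SPACING_S <- 4.5
FIRST_ONSET_S <- 5.0
MIN_ONSET_SPACING_S <- 2.8

#' Subject profile for the synthetic EEG generator
#'
#' Bundles the per-subject parameters that control the simulation: the
#' amplitude scaling of the error-related potential, the background EEG
#' level, the per-condition error probabilities and the trial-to-trial
#' latency jitter of the ErrP.
#'
#' Defaults describe a clean, high signal-to-noise recording: a 1 uV RMS
#' band-limited background against an ErrP template whose error negativity
#' peaks at -5 uV. Error rates default to 0.35 for the fast (short-sequence)
#' condition and 0.20 for the slow (long-sequence) one.
#'
#' @param subject_id character label, e.g. `"02"`.
#' @param errp_gain non-negative multiplier on the ErrP template amplitude.
#'   `0` yields recordings whose labels are independent of the signal.
#' @param noise_rms background EEG RMS amplitude in microvolts (> 0).
#' @param error_rate_fast probability of an error trial under the fast
#'   condition, in `[0, 1]`.
#' @param error_rate_slow probability of an error trial under the slow
#'   condition, in `[0, 1]`.
#' @param latency_jitter_sd standard deviation (ms) of the per-trial shift
#'   of the ErrP peaks.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "01", errp_gain = 1,
                            noise_rms = 1, error_rate_fast = 0.35,
                            error_rate_slow = 0.20,
                            latency_jitter_sd = 10) {
  stopifnot(errp_gain >= 0, noise_rms > 0,
            error_rate_fast >= 0, error_rate_fast <= 1,
            error_rate_slow >= 0, error_rate_slow <= 1,
            latency_jitter_sd >= 0)
  structure(list(subject_id = as.character(subject_id),
                 errp_gain = errp_gain, noise_rms = noise_rms,
                 error_rate_fast = error_rate_fast,
                 error_rate_slow = error_rate_slow,
                 latency_jitter_sd = latency_jitter_sd),
            class = "subject_profile")
}

#' Plan one spelling session
#'
#' Lays out the trial metadata of one session of the speller design (see
#' `?"session-design"`): word and letter counters, cumulative counters since
#' session 1, the per-word flashing condition and the error labels drawn
#' from the condition-specific error rate.
#'
#' @param profile a [subject_profile()].
#' @param session session number, 1-5.
#' @param seed integer seed; the plan is deterministic given
#'   `(profile, session, seed)`.
#' @return A data.frame with one row per feedback period and columns
#'   `subject_id`, `session`, `word_index`, `letter_position`,
#'   `feedback_index`, `total_feedback`, `total_word`, `sequence_type`
#'   (long = 1, short = 0), `is_error`, `onset_time` (seconds).
#' @export
make_session_plan <- function(profile, session, seed) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!(length(session) == 1 && session %in% 1:5)) {
    stop("`session` must be a single integer in 1..5", call. = FALSE)
  }
  n_words <- if (session == 5) 20L else 12L
  withr::with_seed(seed, {
    seq_type <- rbinom(n_words, 1L, 0.5)  # per-word condition, long = 1
    word_index <- rep(seq_len(n_words), each = 5L)
    letter_position <- rep(1:5, times = n_words)
    n <- n_words * 5L
    sequence_type <- seq_type[word_index]
    p_err <- ifelse(sequence_type == 1L,
                    profile$error_rate_slow, profile$error_rate_fast)
    is_error <- rbinom(n, 1L, p_err) == 1L
  })
  feedback_index <- seq_len(n_words * 5L)
  data.frame(
    subject_id = profile$subject_id,
    session = as.integer(session),
    word_index = word_index,
    letter_position = letter_position,
    feedback_index = feedback_index,
    total_feedback = (as.integer(session) - 1L) * 60L + feedback_index,
    total_word = (as.integer(session) - 1L) * 12L + word_index,
    sequence_type = sequence_type,
    is_error = is_error,
    onset_time = FIRST_ONSET_S + (feedback_index - 1L) * TRIAL_SPACING_S,
    stringsAsFactors = FALSE
  )
}

#' Feedback-locked ErrP waveform template
#'
#' Three Gaussian-windowed lobes reproduce the canonical morphology of the
#' interaction error potential: a positive peak near 200 ms after feedback
#' onset, a large error negativity near 250 ms and a positive deflection
#' near 320 ms. Amplitudes before gain are +2, -5 and +3 uV with a common
#' 25 ms lobe width, so the error negativity dominates the difference wave.
#' The template is identically zero before feedback onset.
#'
#' @param time_ms numeric vector of times in ms relative to feedback onset.
#' @param gain non-negative amplitude multiplier; the output is linear in
#'   `gain` and `gain = 0` returns all zeros.
#' @param jitter latency shift in ms applied to all three lobes.
#' @return Numeric vector of amplitudes (uV), same length as `time_ms`.
#' @export
errp_waveform <- function(time_ms, gain = 1, jitter = 0) {
  stopifnot(gain >= 0)
  centers <- c(200, 250, 320) + jitter
  amps <- c(2, -5, 3)
  sd_ms <- 25
  y <- numeric(length(time_ms))
  for (k in seq_along(centers)) {
    y <- y + amps[k] * exp(-((time_ms - centers[k])^2) / (2 * sd_ms^2))
  }
  y <- gain * y
  y[time_ms < 0] <- 0
  y
}

# 1/f ("pink") noise, unit RMS, via spectral shaping of white noise.
# DC is removed; conjugate symmetry is preserved because the shaping is
# symmetric in frequency, so the inverse transform is real.
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  scale <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(fft(X * scale, inverse = TRUE)) / n
  y / sd(y)
}

# Biphasic blink transient sampled at `fs`, peak amplitude `amp` uV,
# total duration 300 ms.
blink_shape <- function(fs, amp) {
  t <- seq(0, 0.3, by = 1 / fs)
  amp * (exp(-((t - 0.09) / 0.035)^2) - 0.35 * exp(-((t - 0.20) / 0.06)^2))
}

new_recording <- function(samples, channel_names, feedback_marker,
                          sampling_rate = FS_HZ) {
  stopifnot(nrow(samples) == length(channel_names),
            ncol(samples) == length(feedback_marker))
  structure(list(sampling_rate = sampling_rate,
                 channel_names = channel_names,
                 samples = samples,
                 feedback_marker = as.integer(feedback_marker)),
            class = "errp_recording")
}

#' @export
print.errp_recording <- function(x, ...) {
  cat(sprintf(
    "<errp_recording> %d channels x %d samples @ %g Hz (%.1f s), %d feedback events\n",
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate, sum(x$feedback_marker)))
  invisible(x)
}

#' Synthesize a continuous recording for one session
#'
#' Renders the session plan into a 200 Hz multichannel recording:
#' spatially correlated pink-noise background on all scalp channels, a
#' 10 Hz alpha rhythm over posterior sites, blink transients on the EOG
#' lead leaking into frontal channels, and -- on error trials only -- the
#' fronto-central ErrP template of [errp_waveform()] weighted by
#' [errp_topography()]. A binary marker track carries a 1 at each feedback
#' onset sample.
#'
#' @param plan a session plan from [make_session_plan()].
#' @param profile the [subject_profile()] used for the plan.
#' @param seed integer seed; output is deterministic given
#'   `(plan, profile, seed)`.
#' @param blink_rate blink arrivals per second (Poisson; default 0.2).
#' @return An `errp_recording` with 56 scalp channels plus `"EOG"`.
#' @export
synthesize_recording <- function(plan, profile, seed, blink_rate = 0.2) {
  stopifnot(inherits(profile, "subject_profile"), nrow(plan) >= 1)
  onsets <- plan$onset_time
  if (any(diff(onsets) < MIN_ONSET_SPACING_S)) {
    stop("invalid plan: feedback onsets must be spaced >= ",
         MIN_ONSET_SPACING_S, " s apart", call. = FALSE)
  }
  fs <- FS_HZ
  scalp <- montage_channels()
  lay <- montage_layout()
  topo <- errp_topography()
  n_ch <- length(scalp)
  n_samp <- ceiling((max(onsets) + 2.0) * fs)
  withr::with_seed(seed, {
    shared <- pink_noise(n_samp)
    samples <- matrix(0, nrow = n_ch + 1L, ncol = n_samp)
    for (c_i in seq_len(n_ch)) {
      own <- pink_noise(n_samp)
      samples[c_i, ] <- profile$noise_rms *
        (sqrt(0.5) * shared + sqrt(0.5) * own)
    }
    # posterior alpha rhythm
    tt <- (seq_len(n_samp) - 1) / fs
    post <- which(lay$y <= -0.6)
    for (c_i in post) {
      phase <- runif(1, 0, 2 * pi)
      amp <- profile$noise_rms * (-lay$y[c_i])  # stronger toward occiput
      samples[c_i, ] <- samples[c_i, ] + amp * sin(2 * pi * 10 * tt + phase)
    }
    # EOG: mild pink background plus blink transients, leaking frontally
    eog <- 0.5 * profile$noise_rms * pink_noise(n_samp)
    n_blinks <- rpois(1, blink_rate * n_samp / fs)
    if (n_blinks > 0) {
      b_times <- sort(runif(n_blinks, 0, n_samp / fs - 0.35))
      leak <- numeric(n_ch)
      leak[match(c("Fp1", "Fp2"), scalp)] <- 0.3
      leak[grep("^AF", scalp)] <- 0.15
      for (bt in b_times) {
        shape <- blink_shape(fs, rnorm(1, 120, 15))
        i0 <- floor(bt * fs) + 1L
        idx <- i0:(i0 + length(shape) - 1L)
        eog[idx] <- eog[idx] + shape
        for (c_i in which(leak > 0)) {
          samples[c_i, idx] <- samples[c_i, idx] + leak[c_i] * shape
        }
      }
    }
    # ErrP on error trials, fronto-central topography
    onset_samp <- round(onsets * fs) + 1L
    t_axis <- seq(0, 600, by = 1000 / fs)  # ms after onset
    for (tr in which(plan$is_error)) {
      jit <- rnorm(1, 0, profile$latency_jitter_sd)
      wave <- errp_waveform(t_axis, gain = profile$errp_gain, jitter = jit)
      idx <- onset_samp[tr]:(onset_samp[tr] + length(wave) - 1L)
      samples[seq_len(n_ch), idx] <- samples[seq_len(n_ch), idx] +
        outer(unname(topo), wave)
    }
  })
  samples[n_ch + 1L, ] <- eog
  marker <- integer(n_samp)
  marker[onset_samp] <- 1L
  new_recording(samples, c(scalp, "EOG"), marker)
}

#' Generate a multi-subject synthetic corpus
#'
#' Builds `n_subjects` subjects, each with the full five-session design
#' (340 trials per subject; see `?"session-design"`). Per-subject and
#' per-session seeds are derived reproducibly from the master seed. Unless
#' a fixed `profile` is supplied, subjects get mildly varied profiles
#' (ErrP gain in 0.8-1.2, noise RMS within 10% of default) around
#' [subject_profile()] defaults.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed master integer seed.
#' @param profile optional fixed [subject_profile()] applied to every
#'   subject (its `subject_id` is overridden per subject).
#' @param plans_only if `TRUE`, skip signal synthesis and return plans only
#'   (fast; useful for design checks).
#' @return A list with one element per subject: `list(profile, sessions)`,
#'   where `sessions` is a list of `list(plan, recording)` (recording is
#'   `NULL` when `plans_only = TRUE`).
#' @export
generate_corpus <- function(n_subjects, seed, profile = NULL,
                            plans_only = FALSE) {
  if (!(length(n_subjects) == 1 && n_subjects >= 1)) {
    stop("`n_subjects` must be >= 1", call. = FALSE)
  }
  n_subjects <- as.integer(n_subjects)
  seeds <- withr::with_seed(seed, {
    matrix(sample.int(2147483646L, n_subjects * 6L), nrow = n_subjects)
  })
  vary <- withr::with_seed(seed + 1L, {
    list(gain = runif(n_subjects, 0.8, 1.2),
         noise = runif(n_subjects, 0.9, 1.1))
  })
  lapply(seq_len(n_subjects), function(s) {
    sid <- sprintf("%02d", s)
    prof <- if (is.null(profile)) {
      subject_profile(subject_id = sid,
                      errp_gain = vary$gain[s],
                      noise_rms = vary$noise[s])
    } else {
      prof2 <- profile
      prof2$subject_id <- sid
      prof2
    }
    sessions <- lapply(1:5, function(sess) {
      plan <- make_session_plan(prof, sess, seed = seeds[s, sess])
      rec <- if (plans_only) NULL else {
        synthesize_recording(plan, prof, seed = seeds[s, 6L] + sess)
      }
      list(plan = plan, recording = rec)
    })
    list(profile = prof, sessions = sessions)
  })
}
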