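prof <- subject_profile("01")

test_that("session plans follow the speller design", {
  p1 <- make_session_plan(prof, 1, seed = 1)
  p5 <- make_session_plan(prof, 5, seed = 1)
  expect_equal(nrow(p1), 60)
  expect_equal(nrow(p5), 100)
  expect_equal(sum(vapply(1:5, function(s) {
    nrow(make_session_plan(prof, s, seed = s))
  }, numeric(1))), 340)
  # counters consistent with the design
  expect_equal(p1$letter_position, rep(1:5, 12))
  expect_equal(p1$word_index, rep(1:12, each = 5))
  expect_equal(p5$total_feedback, 240 + 1:100)
  expect_equal(p5$total_word, 48 + rep(1:20, each = 5))
  expect_true(all(diff(p1$onset_time) > 0))
  expect_true(all(p1$sequence_type %in% c(0, 1)))
  expect_error(make_session_plan(prof, 6, seed = 1), "1..5")
  # determinism
  expect_identical(make_session_plan(prof, 3, seed = 7),
                   make_session_plan(prof, 3, seed = 7))
})

test_that("empirical error fraction matches the configured rates", {
  # pool many sessions; expected rate is the mix of fast/slow conditions
  plans <- do.call(rbind, lapply(1:20, function(i) {
    make_session_plan(prof, (i - 1) %% 5 + 1, seed = 1000 + i)
  }))
  expect_gte(nrow(plans), 1000)
  p_expected <- mean(ifelse(plans$sequence_type == 1,
                            prof$error_rate_slow, prof$error_rate_fast))
  p_hat <- mean(plans$is_error)
  se <- sqrt(p_expected * (1 - p_expected) / nrow(plans))
  expect_lt(abs(p_hat - p_expected), 3 * se)
})

test_that("the ErrP template has the canonical triphasic morphology", {
  t_ms <- seq(-200, 700, by = 1)
  w <- errp_waveform(t_ms)
  expect_true(all(w[t_ms < 0] == 0))
  expect_lt(errp_waveform(250), 0)          # error negativity
  expect_gt(errp_waveform(200), 0)          # leading positivity
  expect_gt(errp_waveform(330), 0)          # trailing positivity
  # dense-grid argmin sits at the negativity latency (the flanking
  # positive lobes shift it a couple of ms right of 250)
  win <- t_ms >= 200 & t_ms <= 320
  t_min <- t_ms[win][which.min(w[win])]
  expect_gte(t_min, 245)
  expect_lte(t_min, 255)
  # linear in gain, zero at gain 0
  expect_equal(errp_waveform(t_ms, gain = 0), numeric(length(t_ms)))
  expect_equal(errp_waveform(t_ms, gain = 2), 2 * w)
})

test_that("synthesized recordings carry markers, rate and determinism", {
  plan <- make_session_plan(prof, 1, seed = 2)[1:10, ]
  rec <- synthesize_recording(plan, prof, seed = 9)
  expect_s3_class(rec, "errp_recording")
  expect_equal(rec$sampling_rate, 200)
  expect_equal(sum(rec$feedback_marker), nrow(plan))
  expect_equal(length(rec$channel_names), 57)
  expect_identical(rec$samples,
                   synthesize_recording(plan, prof, seed = 9)$samples)
  # onsets too close -> invalid plan
  bad <- plan
  bad$onset_time <- seq(1, by = 1, length.out = nrow(bad))
  expect_error(synthesize_recording(bad, prof, seed = 9), "invalid plan")
})

test_that("error minus correct grand average shows the negativity at Cz", {
  hi <- subject_profile("01", errp_gain = 3, noise_rms = 0.5,
                        error_rate_fast = 0.5, error_rate_slow = 0.5,
                        latency_jitter_sd = 0)
  plan <- make_session_plan(hi, 1, seed = 21)
  rec <- synthesize_recording(plan, hi, seed = 22)
  expect_gte(nrow(plan), 50)
  onsets <- which(rec$feedback_marker == 1)
  cz <- which(rec$channel_names == "Cz")
  win <- round(0.23 * 200):round(0.28 * 200)   # 230-280 ms post onset
  avg_win <- function(trials) {
    rowMeans(vapply(onsets[trials], function(o) {
      rec$samples[cz, o + win]
    }, numeric(length(win))))
  }
  diff_wave <- mean(avg_win(which(plan$is_error))) -
    mean(avg_win(which(!plan$is_error)))
  expect_lt(diff_wave, -1)   # clear negative deflection (uV)
})

test_that("corpus generation yields the full trial design per subject", {
  corpus <- generate_corpus(2, seed = 5, plans_only = TRUE)
  expect_length(corpus, 2)
  counts <- vapply(corpus[[1]]$sessions,
                   function(s) nrow(s$plan), numeric(1))
  expect_equal(counts, c(60, 60, 60, 60, 100))
  expect_error(generate_corpus(0, seed = 1), ">= 1")
  # reproducible subject-level derivation
  corpus2 <- generate_corpus(2, seed = 5, plans_only = TRUE)
  expect_identical(corpus[[2]]$sessions[[3]]$plan,
                   corpus2[[2]]$sessions[[3]]$plan)
})

test_that("subject profiles validate their parameters", {
  expect_error(subject_profile(noise_rms = 0))
  expect_error(subject_profile(errp_gain = -1))
  expect_error(subject_profile(error_rate_fast = 1.5))
})
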