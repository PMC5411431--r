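filt <- design_bandpass()
kern <- sg_kernel()

test_that("band-pass magnitude response meets the design template", {
  expect_lt(abs(20 * log10(filter_gain(filt, 5))), 1)      # passband
  expect_gt(20 * log10(filter_gain(filt, 0.5)), -1)
  expect_gt(20 * log10(filter_gain(filt, 9)), -1)
  expect_lte(20 * log10(filter_gain(filt, 0.01)), -50 * 0.99)  # stopbands
  expect_lte(20 * log10(filter_gain(filt, 40)), -50)
  # an elliptic stopband is equiripple, not null: DC sits at the -50 dB
  # floor rather than at exactly zero gain
  expect_lte(filter_gain(filt, 0), 10^(-50 / 20) * 1.05)
  expect_true(all(abs(filt$zpg$pole) < 1))                 # stable
})

test_that("zpk response matches an independent transfer-function grid", {
  # oracle: evaluate the cascaded-biquad transfer function directly
  grid <- seq(0.05, 99, length.out = 1024)
  z <- exp(1i * 2 * pi * grid / filt$fs)
  H <- rep(1 + 0i, length(z))
  for (k in seq_len(nrow(filt$sos))) {
    b <- filt$sos[k, 1:3]
    a <- filt$sos[k, 4:6]
    H <- H * (b[1] + b[2] / z + b[3] / z^2) /
      (a[1] + a[2] / z + a[3] / z^2)
  }
  expect_equal(filter_gain(filt, grid), Mod(H), tolerance = 1e-9)
})

test_that("causal filtering is linear and attenuates per design", {
  tt <- (0:(8 * 200 - 1)) / 200
  zed <- filter_signal(numeric(length(tt)), filt)$y
  expect_equal(zed, numeric(length(tt)))
  s5 <- filter_signal(sin(2 * pi * 5 * tt), filt)$y
  amp5 <- max(abs(s5[(5 * 200):(8 * 200)]))   # steady state after 5 s
  expect_gt(amp5, 10^(-1 / 20))
  expect_lt(amp5, 10^(1 / 20))
  s50 <- filter_signal(sin(2 * pi * 50 * tt), filt)$y
  expect_lt(max(abs(s50[(5 * 200):(8 * 200)])), 10^(-50 / 20) * 1.1)
  # linearity
  x1 <- rnorm(500); x2 <- rnorm(500)
  expect_equal(filter_signal(2 * x1 + 3 * x2, filt)$y,
               2 * filter_signal(x1, filt)$y +
                 3 * filter_signal(x2, filt)$y, tolerance = 1e-8)
})

test_that("chunked filtering with carried state equals one-pass filtering", {
  x <- rnorm(1000)
  full <- filter_signal(x, filt)$y
  zi <- NULL
  parts <- lapply(split(x, rep(1:4, each = 250)), function(chunk) {
    st <- filter_signal(chunk, filt, zi)
    zi <<- st$zi
    st$y
  })
  expect_equal(unlist(parts, use.names = FALSE), full, tolerance = 1e-12)
})

test_that("apply_bandpass filters channels and leaves the marker alone", {
  fx <- make_short_recording(n_trials = 2, seed = 31)
  out <- apply_bandpass(fx$rec, filt)
  expect_identical(out$feedback_marker, fx$rec$feedback_marker)
  expect_equal(out$samples[1, ],
               filter_signal(fx$rec$samples[1, ], filt)$y)
})

test_that("SG kernel matches the normal-equations least-squares oracle", {
  n <- kern$half_window
  # oracle: solve the 31-point cubic least-squares fit explicitly and
  # read off the weight of each sample in the centre evaluation
  G <- outer(-n:n, 0:3, `^`)
  oracle <- (G %*% solve(crossprod(G), t(G)))[n + 1, ]
  expect_equal(kern$coef, unname(oracle), tolerance = 1e-10)
  # symmetry and unit sum (a constant passes through)
  expect_equal(kern$coef, rev(kern$coef))
  expect_equal(sum(kern$coef), 1)
  # impulse response of the smoother is the kernel itself
  imp <- c(numeric(50), 1, numeric(50))
  expect_equal(sg_smooth(imp, kern)[(51 - n):(51 + n)],
               rev(kern$coef), tolerance = 1e-12)
})

test_that("SG smoothing reproduces cubics exactly on interior points", {
  n <- kern$half_window
  withr::with_seed(42, {
    for (rep in 1:5) {
      cf <- rnorm(4)
      tt <- seq_len(120)
      x <- cf[1] + cf[2] * tt + cf[3] * tt^2 + cf[4] * tt^3
      sm <- sg_smooth(x, kern)
      interior <- (n + 1):(120 - n)
      expect_equal(sm[interior], x[interior], tolerance = 1e-6)
    }
  })
  expect_equal(sg_smooth(rep(3.5, 40), kern), rep(3.5, 40))
  expect_error(sg_smooth(rnorm(20), kern), "shorter")
})

test_that("ICA cleaning removes blink leakage and reports components", {
  prof <- subject_profile("01")
  plan <- make_session_plan(prof, 1, seed = 41)[1:16, ]
  rec <- synthesize_recording(plan, prof, seed = 42, blink_rate = 0.5)
  bp <- apply_bandpass(rec, filt)
  cl <- remove_eog(bp, seed = 7)
  fp1 <- which(bp$channel_names == "Fp1")
  eog <- bp$samples[bp$channel_names == "EOG", ]
  before <- abs(cor(bp$samples[fp1, ], eog))
  after <- abs(cor(cl$recording$samples[fp1, ], eog))
  expect_lt(after, before)
  expect_gte(sum(cl$report$removed), 1)
  expect_equal(dim(cl$recording$samples), dim(bp$samples))
  # deterministic given seed
  cl2 <- remove_eog(bp, seed = 7)
  expect_identical(cl$recording$samples, cl2$recording$samples)
})

test_that("ICA is a near-identity when there is nothing to remove", {
  prof <- subject_profile("01")
  plan <- make_session_plan(prof, 1, seed = 43)[1:16, ]
  rec <- synthesize_recording(plan, prof, seed = 44, blink_rate = 0)
  bp <- apply_bandpass(rec, filt)
  cl <- remove_eog(bp, seed = 7)
  rms_in <- apply(bp$samples, 1, sd)
  rms_diff <- apply(cl$recording$samples - bp$samples, 1, sd)
  expect_true(all(rms_diff <= 0.05 * rms_in + 1e-12))
  expect_error(remove_eog(
    new_rec <- {
      r <- bp; r$samples <- r$samples[, 1:2000]
      r$feedback_marker <- r$feedback_marker[1:2000]; r
    }), "60 s")
})
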