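test_that("trial averaging is the pointwise mean", {
  tr <- matrix(rep(sin(seq_len(100) / 5), each = 21), nrow = 21, byrow = FALSE)
  ts <- trialset(matrix(tr, 21, 100), fs = 200)
  expect_equal(average_trials(ts)$samples, tr[1, ])
  v <- rnorm(50)
  ts2 <- trialset(rbind(v, -v), fs = 200)
  expect_equal(average_trials(ts2)$samples, rep(0, 50))
})

test_that("averaging i.i.d. noise shrinks variance by 1/n_trials", {
  set.seed(9)
  n_tr <- 10
  ts <- trialset(matrix(rnorm(n_tr * 1e5, sd = 2), nrow = n_tr), fs = 200)
  out <- average_trials(ts)
  expect_equal(var(out$samples), 4 / n_tr, tolerance = 0.05)
})

test_that("a passband sinusoid survives filtering and decimation", {
  fs <- 20000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  s <- muerg_signal(sin(2 * pi * 10 * t), fs = fs)
  out <- lowpass_resample(s, preprocess_config())
  expect_equal(out$fs, 200)
  expect_length(out$samples, length(t) / 100)
  # amplitude preserved within 1% (compare away from the edges)
  core <- out$samples[50:(length(out$samples) - 50)]
  expect_equal(max(abs(core)), 1, tolerance = 0.01)
})

test_that("a stopband sinusoid is strongly attenuated", {
  fs <- 20000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  s <- muerg_signal(sin(2 * pi * 50 * t), fs = fs)
  out <- lowpass_resample(s, preprocess_config())
  core <- out$samples[50:(length(out$samples) - 50)]  # away from filter edge transients
  expect_lt(max(abs(core)), 0.05)
})

test_that("preprocessing is linear", {
  set.seed(14)
  fs <- 2000
  x <- muerg_signal(rnorm(4000), fs)
  y <- muerg_signal(rnorm(4000), fs)
  cfg <- preprocess_config()
  lhs <- lowpass_resample(muerg_signal(2 * x$samples + 3 * y$samples, fs), cfg)$samples
  rhs <- 2 * lowpass_resample(x, cfg)$samples + 3 * lowpass_resample(y, cfg)$samples
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("post-filter energy above 1.5x the cutoff is below 1%", {
  set.seed(15)
  s <- muerg_signal(rnorm(2^14), fs = 2000)
  out <- lowpass_resample(s, preprocess_config(lp_cutoff = 30, fs_target = 200))
  psd <- welch_psd(out)
  df <- psd$freq[2] - psd$freq[1]
  high <- sum(psd$psd[psd$freq > 45]) * df
  total <- sum(psd$psd) * df
  expect_lt(high / total, 0.01)
})

test_that("preprocess configuration is validated", {
  expect_error(preprocess_config(lp_cutoff = 120, fs_target = 200), "Nyquist")
  s <- muerg_signal(rnorm(1000), fs = 500)
  expect_error(lowpass_resample(s, preprocess_config(fs_target = 201)), "decimation factor")
  slow <- muerg_signal(rnorm(100), fs = 100)
  expect_error(lowpass_resample(slow, preprocess_config(fs_target = 200)), "below the target")
})

test_that("segment_to_length keeps the first n samples", {
  s <- muerg_signal(seq_len(2300), fs = 200)
  out <- segment_to_length(s, 2200)
  expect_length(out$samples, 2200)
  expect_equal(out$samples, as.double(seq_len(2200)))
  same <- muerg_signal(seq_len(2200), fs = 200)
  expect_identical(segment_to_length(same, 2200)$samples, same$samples)
  expect_error(segment_to_length(muerg_signal(1:10, 200), 11), "fewer")
})

test_that("an 11 s surrogate at 200 Hz is exactly the 2200-sample analysis trace", {
  stim <- generate_stimulus(stimulus_spec("natural"), seed = 6)
  ts <- generate_surrogate_response(stim, 0.5, seed = 1)
  s <- lowpass_resample(average_trials(ts), preprocess_config())
  expect_length(segment_to_length(s, 2200)$samples, 2200)
})
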