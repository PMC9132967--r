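test_that("the Welch PSD of a zero signal is identically zero", {
  psd <- welch_psd(rep(0, 1024), fs = 200)
  expect_true(all(psd$psd == 0))
})

test_that("a sinusoid's PSD peaks at its frequency and integrates to A^2/2", {
  fs <- 200
  a <- 1.7
  f0 <- 25  # on a bin centre for window 256: 200/256 * 32
  t <- seq(0, 2^14 / fs, by = 1 / fs)[-1]
  psd <- welch_psd(a * sin(2 * pi * f0 * t), fs = fs)
  expect_equal(psd$freq[which.max(psd$psd)], f0)
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(sum(psd$psd) * df, a^2 / 2, tolerance = 0.02)
})

test_that("white-noise PSD integrates to the signal variance (Parseval)", {
  set.seed(3)
  x <- rnorm(2^15)
  psd <- welch_psd(x, fs = 200)
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(sum(psd$psd) * df, var(x), tolerance = 0.05)
})

test_that("welch arguments are validated", {
  expect_error(welch_psd(rnorm(100), window_size = 256, fs = 200), "exceeds")
  expect_error(welch_psd(rnorm(300), window_size = 128, overlap = 128, fs = 200),
               "overlap")
})

test_that("self-coherence is 1 at every frequency with power", {
  s <- generate_pink_noise(2^12, seed = 8, fs = 200)
  coh <- coherence(s, s)
  expect_true(all(coh$coherence > 1 - 1e-10))
  expect_true(all(coh$coherence <= 1))
})

test_that("coherence is symmetric in its arguments", {
  x <- generate_pink_noise(2^12, seed = 1, fs = 200)
  y <- generate_uniform_noise(2^12, seed = 2, fs = 200)
  expect_equal(coherence(x, y)$coherence, coherence(y, x)$coherence, tolerance = 1e-12)
})

test_that("independent noises sit near the segment-count coherence floor", {
  x <- generate_uniform_noise(2^14, seed = 3, fs = 200)
  y <- generate_uniform_noise(2^14, seed = 4, fs = 200)
  coh <- coherence(x, y)
  # 127 half-overlapping segments: mean null coherence ~ 1/64
  expect_lt(mean(coh$coherence), 0.05)
})

test_that("a noiseless band-limited filter of x is coherent in its passband", {
  set.seed(5)
  x <- muerg_signal(rnorm(2^14), fs = 200)
  y <- muerg_signal(lowpass_filter(x$samples, 200, cutoff = 30), fs = 200)
  coh <- coherence(x, y)
  inband <- coh$freq > 2 & coh$freq < 25
  expect_gt(min(coh$coherence[inband]), 0.99)
})

test_that("degenerate and mismatched coherence inputs raise errors", {
  x <- muerg_signal(rnorm(300), fs = 200)
  expect_error(coherence(x, muerg_signal(rnorm(300), fs = 100)), "Sampling rates")
  expect_error(coherence(x, muerg_signal(rnorm(299), fs = 200)), "length")
  expect_error(coherence(muerg_signal(rnorm(256), 200), muerg_signal(rnorm(256), 200),
                         window_size = 256), "at least 2")
})
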