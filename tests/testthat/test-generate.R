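test_that("seeded generators are reproducible and leave the global RNG alone", {
  u1 <- generate_uniform_noise(4, seed = 5)
  u2 <- generate_uniform_noise(4, seed = 5)
  expect_identical(u1$samples, u2$samples)
  set.seed(1)
  before <- rnorm(1)
  set.seed(1)
  invisible(generate_pink_noise(64, seed = 9))
  expect_identical(rnorm(1), before)
  expect_error(generate_uniform_noise(0, 1), "positive integer")
  expect_error(generate_pink_noise(8, 1), ">= 16")
})

test_that("uniform noise has the moments of U(-1, 1)", {
  n <- 1e5
  x <- generate_uniform_noise(n, seed = 2)$samples
  sigma <- sqrt(1 / 3)
  expect_lt(abs(mean(x)), 3 * sigma / sqrt(n))
  expect_lt(abs(var(x) - 1 / 3) / (1 / 3), 0.05)
  expect_true(all(abs(x) <= 1))
})

test_that("pink noise has a 1/f Welch spectrum", {
  s <- generate_pink_noise(2^14, seed = 3)
  expect_equal(mean(s$samples), 0, tolerance = 1e-12)
  expect_equal(sd(s$samples), 1, tolerance = 1e-9)
  slope <- psd_slope(welch_psd(s, window_size = 1024, overlap = 512))
  expect_equal(slope, -1, tolerance = 0.1)
})

test_that("the pink PSD slope stays in [-1.15, -0.85] across 20 seeds", {
  slopes <- vapply(1:20, function(sd) {
    psd_slope(welch_psd(generate_pink_noise(2^14, seed = sd),
                        window_size = 1024, overlap = 512))
  }, numeric(1))
  expect_true(all(slopes > -1.15 & slopes < -0.85))
})

test_that("different seeds give distinct traces drawn from the same law", {
  a <- generate_pink_noise(2^12, seed = 1)
  b <- generate_pink_noise(2^12, seed = 2)
  expect_false(identical(a$samples, b$samples))
  sa <- psd_slope(welch_psd(a, 512, 256))
  sb <- psd_slope(welch_psd(b, 512, 256))
  expect_equal(sa, sb, tolerance = 0.3)
})

test_that("the chirp stimulus has the protocol's segment structure", {
  spec <- stimulus_spec("chirp")
  stim <- generate_stimulus(spec)
  expect_equal(length(stim) / stim$fs, 35, tolerance = 1)
  on_idx <- seq_len(round(spec$on_flash_s * spec$fs))
  expect_true(all(stim$samples[on_idx] == 1))              # ON step at max intensity
  off_idx <- round(spec$on_flash_s * spec$fs) + seq_len(round(spec$off_dark_s * spec$fs) - 1)
  expect_true(all(stim$samples[off_idx] == 0))             # OFF dark period
  expect_true(all(stim$samples >= 0 & stim$samples <= 1))  # luminance bounds
  expect_error(stimulus_spec("chirp", total_s = 20), "Segment durations")
})

test_that("the natural-like stimulus is a 2200-sample nonnegative luminance trace", {
  stim <- generate_stimulus(stimulus_spec("natural"), seed = 4)
  expect_length(stim$samples, 2200)
  expect_equal(stim$fs, 200)
  expect_true(all(stim$samples >= 0 & stim$samples <= 1))
  expect_error(generate_stimulus(stimulus_spec("natural")), "seed")
})

test_that("noiseless surrogates are stimulus-locked; pure-noise surrogates are not", {
  stim <- generate_stimulus(stimulus_spec("natural"), seed = 10)
  clean <- generate_surrogate_response(stim, snr_mix = 0, seed = 1, white_sd = 0)
  avg <- average_trials(clean)
  expect_equal(nrow(clean$trials), 21)
  # all trials identical to the deterministic response
  expect_equal(max(abs(sweep(clean$trials, 2, avg$samples))), 0, tolerance = 1e-12)
  # segments must outlast the ~2 s response kernel for an unbiased estimate
  coh <- coherence(stim, avg, window_size = 1024, overlap = 512)
  passband <- coh$freq > 0.3 & coh$freq < 1.6
  expect_gt(mean(coh$coherence[passband]), 0.9)

  noisy <- generate_surrogate_response(stim, snr_mix = 1, seed = 1)
  coh_n <- coherence(stim, average_trials(noisy))
  pb256 <- coh_n$freq > 0.3 & coh_n$freq < 1.6
  # null ceiling: coherence between the stimulus and independent draws
  null <- replicate(20, {
    a <- generate_pink_noise(2200, seed = sample.int(1e6, 1), fs = 200)
    mean(coherence(stim, a)$coherence[pb256])
  })
  expect_lt(mean(coh_n$coherence[pb256]), max(null) + 0.05)
  expect_error(generate_surrogate_response(stim, snr_mix = 2, seed = 1), "snr_mix")
})

test_that("surrogate trial sets differ across seeds but share their law", {
  stim <- generate_stimulus(stimulus_spec("natural"), seed = 10)
  a <- generate_surrogate_response(stim, 0.5, seed = 1)
  b <- generate_surrogate_response(stim, 0.5, seed = 2)
  expect_false(identical(a$trials, b$trials))
  expect_equal(dim(a$trials), dim(b$trials))
  expect_equal(sd(a$trials), sd(b$trials), tolerance = 0.15)
})

test_that("cohort generation is a pure function of its spec", {
  groups <- tibble::tibble(label = c("lo", "hi"), n_subjects = c(2, 2),
                           complexity_offset = c(0.2, 0.8), sex_ratio = 0.5)
  c1 <- generate_cohort(cohort_spec(groups, seed = 42))
  c2 <- generate_cohort(cohort_spec(groups, seed = 42))
  expect_identical(c1$snr_mix, c2$snr_mix)
  expect_identical(c1$sex, c2$sex)
  expect_identical(c1$trials[[3]]$trials, c2$trials[[3]]$trials)
  expect_equal(nrow(c1), 4)
  expect_equal(nrow(c1$trials[[1]]$trials), 21)
})

test_that("cohort specs validate group tables", {
  bad <- tibble::tibble(label = c("a", "a"), n_subjects = 2,
                        complexity_offset = 0.5, sex_ratio = 0.5)
  expect_error(cohort_spec(bad), "Duplicate group labels")
  empty <- tibble::tibble(label = "a", n_subjects = 0,
                          complexity_offset = 0.5, sex_ratio = 0.5)
  expect_error(cohort_spec(empty), "at least one subject")
  one <- generate_cohort(cohort_spec(tibble::tibble(
    label = "solo", n_subjects = 1, complexity_offset = 0.5, sex_ratio = 1
  ), seed = 3))
  expect_equal(nrow(one), 1)
  expect_s3_class(one$trials[[1]], "trialset")
})

test_that("uniform noise loses entropy at large scales while pink noise keeps it", {
  ok_decay <- ok_gap <- 0
  for (sd in 1:8) {
    cu <- mse_curve(generate_uniform_noise(2200, sd), tau_max = 44)
    cp <- mse_curve(generate_pink_noise(2200, sd), tau_max = 44)
    ok_decay <- ok_decay + (cu$entropy[40] < cu$entropy[10])
    ok_gap <- ok_gap + (cp$entropy[40] > cu$entropy[40] + 0.3)
  }
  expect_equal(ok_decay, 8)
  expect_equal(ok_gap, 8)
})

test_that("surrogate responses have near-zero entropy at the smallest scales", {
  # band-limited, smooth retinal traces: variation below the 7-sample
  # (ceil(200/30)) horizon is minimal, so the curve rises from ~0
  stim <- generate_stimulus(stimulus_spec("natural"), seed = 10)
  for (snr in c(0.2, 0.5)) {
    ts <- generate_surrogate_response(stim, snr_mix = snr, seed = 2)
    s <- lowpass_resample(average_trials(ts), preprocess_config())
    cv <- mse_curve(s, tau_max = 10)
    expect_lt(cv$entropy[1], 0.3)
    expect_gt(cv$entropy[10], cv$entropy[1] + 0.2)
  }
})
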