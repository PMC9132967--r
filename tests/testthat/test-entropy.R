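test_that("coarse-graining averages non-overlapping windows and drops the tail", {
  expect_equal(coarse_grain(1:6, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(1:7, 3), c(2, 5))
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(1:5, 2, offset = 1), c(2.5, 4.5))
  expect_equal(coarse_grain(1:6, 2, offset = 0), coarse_grain(1:6, 2))
  expect_error(coarse_grain(1:5, 6), "exceeds")
  expect_error(coarse_grain(1:5, 2, offset = 2), "offset")
})

test_that("all tau offset grains have the book-kept lengths", {
  set.seed(41)
  x <- rnorm(503)
  for (tau in c(2, 5, 7)) {
    for (k in 0:(tau - 1)) {
      expect_length(coarse_grain(x, tau, k), (length(x) - k) %/% tau)
      expect_equal(coarse_grain(x, tau, k), naive_grain(x, tau, k))
    }
  }
})

test_that("sample entropy is zero for perfectly regular series", {
  expect_equal(suppressWarnings(sample_entropy(rep(3.7, 40))), 0)
  alt <- rep(c(1, -1), 60)
  expect_equal(sample_entropy(alt, m = 2, r = 0.2), 0)
})

test_that("fuzzy membership follows the quadratic exponential", {
  expect_equal(fuzzy_membership(0, r = 0.2), 1)
  expect_equal(fuzzy_membership(0.2, r = 0.2), exp(-1))
  expect_lt(fuzzy_membership(0.4, r = 0.2), fuzzy_membership(0.2, r = 0.2))
  expect_equal(fuzzy_membership(0.3, r = 0.5, convention = "chen_original"),
               exp(-0.09 / 0.5))
  expect_error(fuzzy_membership(-1, 0.2), "non-negative")
})

test_that("fast estimators match the brute-force references", {
  set.seed(7)
  for (i in 1:6) {
    n <- sample(80:200, 1)
    x <- runif(n, -1, 1)
    expect_equal(suppressWarnings(sample_entropy(x)), naive_entropy(x, fuzzy = FALSE),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(fuzzy_entropy(x)), naive_entropy(x, fuzzy = TRUE),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(fuzzy_entropy(x, demean = FALSE)),
                 naive_entropy(x, fuzzy = TRUE, demean = FALSE), tolerance = 1e-12)
    expect_equal(suppressWarnings(fuzzy_entropy(x, convention = "chen_original")),
                 naive_entropy(x, convention = "chen_original"), tolerance = 1e-12)
  }
})

test_that("fuzzy entropy is invariant to offset and positive scaling", {
  set.seed(11)
  x <- rnorm(300)
  base <- fuzzy_entropy(x)
  expect_equal(fuzzy_entropy(x + 17.3), base, tolerance = 1e-10)
  expect_equal(fuzzy_entropy(3.5 * x), base, tolerance = 1e-10)
  expect_equal(fuzzy_entropy(rep(5, 100)), 0)
})

test_that("fuzzy entropy varies smoothly with the threshold r", {
  set.seed(12)
  x <- rnorm(400)
  vals <- vapply(seq(0.1, 0.5, by = 0.05), function(r) fuzzy_entropy(x, r = r),
                 numeric(1))
  expect_true(all(diff(vals) < 0))            # wider tolerance, lower entropy
  expect_true(all(abs(diff(vals)) < 0.5))     # no jumps on a fine grid
})

test_that("multiscale curves at scale 1 equal the base entropy exactly", {
  set.seed(21)
  x <- rnorm(200)
  for (method in c("mse", "cmse", "rcmse")) {
    cv <- suppressWarnings(mse_curve(x, tau_max = 1, method = method))
    expect_identical(cv$entropy, suppressWarnings(fuzzy_entropy(x)))
    cs <- suppressWarnings(mse_curve(x, tau_max = 1, method = method, entropy = "sample"))
    expect_identical(cs$entropy, suppressWarnings(sample_entropy(x)))
  }
})

test_that("multiscale curves match a naive all-offsets implementation", {
  set.seed(33)
  x <- runif(600, -1, 1)
  for (method in c("mse", "cmse", "rcmse")) {
    for (fuzzy in c(TRUE, FALSE)) {
      got <- suppressWarnings(mse_curve(x, tau_max = 12, method = method,
                                        entropy = if (fuzzy) "fuzzy" else "sample"))
      want <- naive_mse(x, tau_max = 12, method = method, fuzzy = fuzzy)
      expect_equal(got$entropy, want, tolerance = 1e-10)
    }
  }
})

test_that("entropy is non-negative wherever defined", {
  set.seed(55)
  for (i in 1:10) {
    x <- switch(1 + i %% 3,
                rnorm(400), runif(400), cumsum(rnorm(400)))
    cv <- suppressWarnings(mse_curve(x, tau_max = 8))
    expect_true(all(cv$entropy[cv$defined] >= 0))
  }
})

test_that("refined compositing yields fewer undefined scales than plain compositing", {
  set.seed(66)
  und_c <- und_r <- 0
  for (i in 1:10) {
    x <- runif(300, -1, 1)
    cc <- suppressWarnings(mse_curve(x, tau_max = 50, method = "cmse", entropy = "sample"))
    cr <- suppressWarnings(mse_curve(x, tau_max = 50, method = "rcmse", entropy = "sample"))
    und_c <- und_c + sum(!cc$defined)
    und_r <- und_r + sum(!cr$defined)
  }
  expect_lt(und_r, und_c)
})

test_that("the default maximum scale follows the floor(N / 50) rule", {
  set.seed(77)
  cv <- mse_curve(rnorm(2200))
  expect_equal(max(cv$scale), 44)
  cv2 <- suppressWarnings(mse_curve(rnorm(300)))
  expect_equal(max(cv2$scale), 6)
})

test_that("complexity index sums the inclusive scale window", {
  unit <- tibble::tibble(scale = 1:44, entropy = rep(1, 44))
  expect_equal(complexity_index(unit)$index, 25)
  expect_equal(complexity_index(unit)$n_scales, 25)
  zero <- tibble::tibble(scale = 1:44, entropy = rep(0, 44))
  expect_equal(complexity_index(zero)$index, 0)
  ramp <- tibble::tibble(scale = 1:44, entropy = (1:44) / 44)
  expect_equal(complexity_index(ramp)$index, 800 / 44)
})

test_that("undefined entropy inside the window is an error naming the scales", {
  cv <- tibble::tibble(scale = 1:44, entropy = c(rep(1, 29), NA, rep(1, 14)))
  expect_error(complexity_index(cv), "scale\\(s\\) 30")
  short <- tibble::tibble(scale = 1:30, entropy = rep(1, 30))
  expect_error(complexity_index(short), "lacks scales")
  expect_error(complexity_index(cv, 30, 20), "scale_lo")
})

test_that("short series warn rather than fail", {
  set.seed(88)
  expect_warning(sample_entropy(rnorm(30)), "below the recommended minimum")
  expect_warning(mse_curve(rnorm(200), tau_max = 8), "below the recommended minimum")
})
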