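# periodic Hann window of length w
hann_window <- function(w) 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / w))

# Welch segment-averaged spectra. Returns one-sided frequency axis plus
# averaged auto-spectra (and cross-spectrum when y is supplied), density
# scaling (units^2 / Hz), constant detrend per segment.
welch_spectra <- function(x, y = NULL, fs, window_size, overlap) {
  N <- length(x)
  window_size <- as.integer(window_size)
  overlap <- as.integer(overlap)
  if (window_size < 2L) abort("`window_size` must be at least 2 samples.")
  if (window_size > N) {
    abort(sprintf("`window_size` (%d) exceeds the signal length (%d).", window_size, N))
  }
  if (overlap < 0L || overlap >= window_size) abort("`overlap` must be in [0, window_size).")
  step <- window_size - overlap
  starts <- seq.int(1L, N - window_size + 1L, by = step)
  win <- hann_window(window_size)
  scale <- 1 / (fs * sum(win^2))
  nfreq <- window_size %/% 2L + 1L
  pxx <- numeric(nfreq)
  pyy <- if (!is.null(y)) numeric(nfreq) else NULL
  pxy <- if (!is.null(y)) complex(nfreq) else NULL
  for (s0 in starts) {
    idx <- s0:(s0 + window_size - 1L)
    xs <- x[idx]
    xs <- (xs - mean(xs)) * win
    X <- fft(xs)[seq_len(nfreq)]
    pxx <- pxx + Re(X * Conj(X))
    if (!is.null(y)) {
      ys <- y[idx]
      ys <- (ys - mean(ys)) * win
      Y <- fft(ys)[seq_len(nfreq)]
      pyy <- pyy + Re(Y * Conj(Y))
      pxy <- pxy + Conj(X) * Y
    }
  }
  k <- length(starts)
  one_sided <- function(p) {
    p <- p * scale / k
    # double everything except DC and (for even windows) the Nyquist bin
    dbl <- 2:(nfreq - if (window_size %% 2L == 0L) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    p
  }
  list(freq = (seq_len(nfreq) - 1) * fs / window_size,
       pxx = one_sided(pxx),
       pyy = if (!is.null(y)) one_sided(pyy) else NULL,
       # cross-spectrum kept unscaled: coherence is a ratio
       pxy_raw = pxy, pxx_raw = pxx, pyy_raw = pyy,
       n_segments = k)
}

#' Welch power spectral density
#'
#' Averaged periodogram over overlapping, Hann-windowed,
#' constant-detrended segments; one-sided density scaling, so the PSD
#' integrates to the signal variance (Parseval). Defaults (window 256,
#' overlap 128) match the frequency-domain characterization the package
#' reproduces.
#'
#' @param s A [muerg_signal()] or numeric vector (then supply `fs`).
#' @param window_size Segment length in samples (default 256).
#' @param overlap Overlap between consecutive segments in samples
#'   (default 128).
#' @param fs Sampling rate (Hz) when `s` is a bare vector.
#' @return A tibble of class `welch_psd` with columns `freq` (Hz) and
#'   `psd` (units^2/Hz); `window_size`, `overlap` and `n_segments` are
#'   attached as attributes.
#' @examples
#' s <- generate_uniform_noise(2^12, seed = 1, fs = 200)
#' psd <- welch_psd(s)
#' sum(psd$psd) * (psd$freq[2] - psd$freq[1])   # ~ var(s$samples) = 1/3
#' @export
welch_psd <- function(s, window_size = 256, overlap = 128, fs = NULL) {
  fs <- resolve_fs(s, fs)
  x <- as_samples(s, "s")
  w <- welch_spectra(x, NULL, fs, window_size, overlap)
  out <- tibble(freq = w$freq, psd = w$pxx)
  class(out) <- c("welch_psd", class(out))
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "overlap") <- as.integer(overlap)
  attr(out, "n_segments") <- w$n_segments
  attr(out, "fs") <- fs
  out
}

#' Magnitude-squared coherence
#'
#' Frequency-wise linear coupling between a stimulus and a response,
#' `C_xy(f) = |P_xy|^2 / (P_x P_y)`, with all three spectra estimated by
#' Welch's method on the same segmentation. Values are clipped to \[0, 1\]
#' against floating-point excursions. At least two segments are required:
#' a single segment gives the degenerate estimate 1 everywhere.
#'
#' @param x,y Signals of equal length and sampling rate
#'   ([muerg_signal()] or numeric vectors with `fs`).
#' @inheritParams welch_psd
#' @return A tibble of class `coherence_estimate` with columns `freq` (Hz)
#'   and `coherence` (dimensionless, in \[0, 1\]).
#' @examples
#' s <- generate_pink_noise(2^12, seed = 2, fs = 200)
#' coh <- coherence(s, s)
#' all(coh$coherence > 0.999)
#' @export
coherence <- function(x, y, window_size = 256, overlap = 128, fs = NULL) {
  fs_x <- resolve_fs(x, fs)
  fs_y <- resolve_fs(y, fs)
  if (fs_x != fs_y) abort(sprintf("Sampling rates differ: %g vs %g Hz.", fs_x, fs_y))
  xv <- as_samples(x, "x")
  yv <- as_samples(y, "y")
  if (length(xv) != length(yv)) {
    abort(sprintf("Signals differ in length: %d vs %d samples.", length(xv), length(yv)))
  }
  w <- welch_spectra(xv, yv, fs_x, window_size, overlap)
  if (w$n_segments < 2L) {
    abort("Coherence needs at least 2 Welch segments; a single segment is identically 1.")
  }
  cxy <- Mod(w$pxy_raw)^2 / (w$pxx_raw * w$pyy_raw)
  cxy[!is.finite(cxy)] <- 0
  cxy <- pmin(pmax(cxy, 0), 1)
  out <- tibble(freq = w$freq, coherence = cxy)
  class(out) <- c("coherence_estimate", class(out))
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "overlap") <- as.integer(overlap)
  attr(out, "n_segments") <- w$n_segments
  attr(out, "fs") <- fs_x
  out
}

#' Log-log slope of a power spectral density
#'
#' Ordinary least-squares slope of `log10(psd)` against `log10(freq)` over
#' a frequency band, the standard check that a synthesized 1/f noise
#' actually has spectral exponent -1.
#'
#' @param psd A [welch_psd()] result.
#' @param f_lo,f_hi Band endpoints (Hz); defaults span from ten
#'   fundamental frequencies above DC to a quarter of the sampling rate.
#' @return The fitted slope (dimensionless).
#' @export
psd_slope <- function(psd, f_lo = NULL, f_hi = NULL) {
  fs <- attr(psd, "fs")
  if (is.null(f_lo)) f_lo <- psd$freq[2] * 2
  if (is.null(f_hi)) f_hi <- fs / 4
  sel <- psd$freq >= f_lo & psd$freq <= f_hi & psd$psd > 0
  if (sum(sel) < 3) abort("Too few frequency bins in the requested band.")
  unname(coef(lm(log10(psd$psd[sel]) ~ log10(psd$freq[sel])))[2])
}
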