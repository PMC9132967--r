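#' Preprocessing configuration
#'
#' Parameters of the trace-conditioning step that turns a raw averaged
#' recording into the analysis-ready signal: a low-pass (anti-alias)
#' Butterworth filter followed by decimation. Defaults reproduce the
#' recording pipeline the package emulates: 30 Hz cutoff, 200 Hz target
#' rate, order-4 filter applied forward-backward (zero phase, so response
#' latencies are preserved).
#'
#' @param lp_cutoff Low-pass cutoff (Hz), must be below `fs_target / 2`.
#' @param fs_target Output sampling rate (Hz).
#' @param filter_order Butterworth order (the forward-backward pass doubles
#'   the effective order).
#' @param zero_phase Apply the filter forward-backward (`TRUE`, default) or
#'   forward only.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(lp_cutoff = 30, fs_target = 200,
                              filter_order = 4, zero_phase = TRUE) {
  if (lp_cutoff <= 0) abort("`lp_cutoff` must be positive.")
  if (fs_target <= 0) abort("`fs_target` must be positive.")
  if (lp_cutoff >= fs_target / 2) {
    abort(sprintf("Cutoff %g Hz is not below the target Nyquist rate %g Hz.",
                  lp_cutoff, fs_target / 2))
  }
  structure(list(lp_cutoff = lp_cutoff, fs_target = fs_target,
                 filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

#' Average the trials of a trial set
#'
#' Pointwise mean across repetitions; the sampling rate and metadata are
#' unchanged. Averaging over the repeated presentations suppresses
#' trial-independent noise by `1/n_trials` in variance while preserving the
#' stimulus-locked response.
#'
#' @param t A [trialset()].
#' @return A [muerg_signal()] labelled with the subject id.
#' @examples
#' ts <- trialset(rbind(c(1, 2), c(3, 4)), fs = 200)
#' average_trials(ts)$samples   # 2 3
#' @export
average_trials <- function(t) {
  if (!inherits(t, "trialset")) abort("`t` must be a trialset.")
  muerg_signal(colMeans(t$trials), t$fs,
               label = if (nzchar(t$subject)) t$subject else t$protocol)
}

# order-`order` Butterworth low-pass, optionally zero-phase (filtfilt)
lowpass_filter <- function(x, fs, cutoff, order = 4, zero_phase = TRUE) {
  if (cutoff >= fs / 2) abort(sprintf("Cutoff %g Hz >= Nyquist %g Hz.", cutoff, fs / 2))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (zero_phase) {
    as.double(signal::filtfilt(bf, x))
  } else {
    as.double(signal::filter(bf, x))
  }
}

#' Low-pass filter and resample a signal
#'
#' Anti-alias filtering precedes decimation: the signal is low-pass
#' filtered at `cfg$lp_cutoff`, then every `fs / fs_target`-th sample is
#' kept. The decimation factor must be an integer (the use case this
#' models is 20 kHz -> 200 Hz, factor 100). With `zero_phase` (default)
#' the filter runs forward and backward, so there is no group delay.
#'
#' @param s A [muerg_signal()] with `fs >= cfg$fs_target`.
#' @param cfg A [preprocess_config()].
#' @return A [muerg_signal()] at `cfg$fs_target`.
#' @examples
#' t <- seq(0, 1, by = 1 / 2000)
#' s <- muerg_signal(sin(2 * pi * 10 * t), fs = 2000)
#' lowpass_resample(s, preprocess_config())
#' @export
lowpass_resample <- function(s, cfg = preprocess_config()) {
  if (!inherits(s, "muerg_signal")) abort("`s` must be a muerg_signal.")
  if (!inherits(cfg, "preprocess_config")) abort("`cfg` must be a preprocess_config.")
  if (s$fs < cfg$fs_target) {
    abort(sprintf("Signal rate %g Hz is below the target %g Hz.", s$fs, cfg$fs_target))
  }
  if (cfg$lp_cutoff >= s$fs / 2) {
    abort(sprintf("Cutoff %g Hz is not below the signal's Nyquist rate %g Hz.",
                  cfg$lp_cutoff, s$fs / 2))
  }
  factor <- s$fs / cfg$fs_target
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf("Non-integer decimation factor %g (fs %g Hz -> %g Hz); resample to an integer divisor first.",
                  factor, s$fs, cfg$fs_target))
  }
  factor <- as.integer(round(factor))
  y <- lowpass_filter(s$samples, s$fs, cfg$lp_cutoff, cfg$filter_order, cfg$zero_phase)
  if (factor > 1L) y <- y[seq(1L, length(y), by = factor)]
  muerg_signal(y, cfg$fs_target, label = s$label)
}

#' Truncate a signal to a fixed length
#'
#' Keeps the first `n` samples, the convention used to align responses of
#' slightly different durations to a common analysis length (2200 samples
#' for the 11 s natural-image protocol at 200 Hz).
#'
#' @param s A [muerg_signal()] with at least `n` samples.
#' @param n Target length.
#' @return A [muerg_signal()] of exactly `n` samples.
#' @export
segment_to_length <- function(s, n) {
  if (!inherits(s, "muerg_signal")) abort("`s` must be a muerg_signal.")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  if (length(s$samples) < n) {
    abort(sprintf("Signal has %d samples, fewer than the requested %d.", length(s$samples), n))
  }
  muerg_signal(s$samples[seq_len(n)], s$fs, s$label)
}
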