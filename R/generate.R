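#' Generate seeded uniform white noise
#'
#' I.i.d. samples uniform on \[-1, 1\] (zero population mean, variance
#' 1/3). Uniform noise is the canonical "simple" signal whose multiscale
#' entropy decays at large scales, the negative control of the noise
#' validation.
#'
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param fs Sampling rate attached to the result (Hz, default 200).
#' @return A [muerg_signal()].
#' @examples
#' identical(generate_uniform_noise(4, 1)$samples, generate_uniform_noise(4, 1)$samples)
#' @export
generate_uniform_noise <- function(n, seed, fs = 200) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  x <- withr::with_seed(seed, runif(n, -1, 1))
  muerg_signal(x, fs, "uniform noise")
}

#' Generate seeded 1/f (pink) noise
#'
#' Spectral synthesis: Fourier amplitudes proportional to `f^(-1/2)` (so
#' power falls as 1/f), i.i.d. uniform random phases, inverse transform;
#' the result is centred and normalized to unit sample variance. Pink noise
#' is the canonical "complex" signal whose irregularity persists across
#' coarse-graining scales, the positive control of the noise validation.
#'
#' @param n Number of samples (>= 16, required by the spectral synthesis).
#' @inheritParams generate_uniform_noise
#' @return A [muerg_signal()].
#' @examples
#' p <- generate_pink_noise(2^12, seed = 3)
#' @export
generate_pink_noise <- function(n, seed, fs = 200) {
  n <- as.integer(n)
  if (is.na(n) || n < 16L) abort("`n` must be an integer >= 16 for spectral synthesis.")
  half <- n %/% 2L
  x <- withr::with_seed(seed, {
    amp <- (1:half)^(-0.5)
    ph <- runif(half, 0, 2 * pi)
    pos <- complex(modulus = amp, argument = ph)
    if (n %% 2L == 0L) {
      # even n: bin `half` is the Nyquist bin and must be real
      pos[half] <- complex(modulus = amp[half], argument = 0)
      spec <- c(0, pos, Conj(rev(pos[-half])))
    } else {
      spec <- c(0, pos, Conj(rev(pos)))
    }
    Re(fft(spec, inverse = TRUE))
  })
  x <- x - mean(x)
  x <- x / sd(x)
  muerg_signal(x, fs, "pink noise")
}

#' Specify a visual stimulus
#'
#' Two protocols are modelled. The chirp stimulus (`"chirp"`, CS protocol)
#' is an ON light step (3 s at maximum intensity), an OFF dark period
#' (3 s), a constant-amplitude sinusoid sweeping linearly from 1 to 10 Hz,
#' then a 1 Hz sinusoid with linearly increasing amplitude; defaults total
#' ~35 s at 200 Hz. The natural-like protocol (`"natural"`, NI) is a
#' nonnegative 1/f-distributed luminance series standing in for a natural
#' movie's intensity statistics; defaults give 11 s x 200 Hz = 2200
#' samples.
#'
#' @param protocol `"chirp"` or `"natural"`.
#' @param on_flash_s,off_dark_s ON step and OFF dark durations (s).
#' @param sweep_f_lo,sweep_f_hi Sweep frequency endpoints (Hz).
#' @param sweep_s Sweep duration (s).
#' @param am_freq,am_s Amplitude-ramp sinusoid frequency (Hz) and duration (s).
#' @param total_s Total duration (s).
#' @param fs Sampling rate (Hz); must exceed `2 * sweep_f_hi`.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(protocol = c("chirp", "natural"),
                          on_flash_s = 3, off_dark_s = 3,
                          sweep_f_lo = 1, sweep_f_hi = 10, sweep_s = 15,
                          am_freq = 1, am_s = 14,
                          total_s = NULL, fs = 200) {
  protocol <- match.arg(protocol)
  if (is.null(total_s)) {
    total_s <- if (protocol == "chirp") on_flash_s + off_dark_s + sweep_s + am_s else 11
  }
  if (total_s <= 0) abort("`total_s` must be positive.")
  if (fs <= 2 * sweep_f_hi) abort("`fs` must exceed twice the highest sweep frequency.")
  if (protocol == "chirp") {
    segs <- on_flash_s + off_dark_s + sweep_s + am_s
    if (abs(segs - total_s) > 1e-9) {
      abort(sprintf("Segment durations sum to %g s but total_s = %g s.", segs, total_s))
    }
  }
  structure(list(protocol = protocol, on_flash_s = on_flash_s,
                 off_dark_s = off_dark_s, sweep_f_lo = sweep_f_lo,
                 sweep_f_hi = sweep_f_hi, sweep_s = sweep_s,
                 am_freq = am_freq, am_s = am_s, total_s = total_s, fs = fs),
            class = "stimulus_spec")
}

#' Generate a stimulus luminance trace
#'
#' Renders a [stimulus_spec()] to a nonnegative luminance signal in
#' \[0, 1\]. The natural-like protocol needs a `seed` (its luminance is a
#' rescaled pink-noise draw); the chirp is deterministic.
#'
#' @param spec A [stimulus_spec()].
#' @param seed Integer seed (required for `"natural"`).
#' @return A [muerg_signal()] with `fs = spec$fs`.
#' @examples
#' stim <- generate_stimulus(stimulus_spec("chirp"))
#' length(stim) / stim$fs   # ~35 s
#' @export
generate_stimulus <- function(spec = stimulus_spec(), seed = NULL) {
  if (!inherits(spec, "stimulus_spec")) abort("`spec` must be a stimulus_spec.")
  fs <- spec$fs
  if (spec$protocol == "natural") {
    n <- round(spec$total_s * fs)
    if (is.null(seed)) abort("The natural-like stimulus requires a `seed`.")
    p <- generate_pink_noise(n, seed, fs)$samples
    x <- (p - min(p)) / (max(p) - min(p))  # rectify/rescale to [0, 1]
    return(muerg_signal(x, fs, "natural-like stimulus"))
  }
  n_on <- round(spec$on_flash_s * fs)
  n_off <- round(spec$off_dark_s * fs)
  n_sw <- round(spec$sweep_s * fs)
  n_am <- round(spec$am_s * fs)
  t_sw <- (seq_len(n_sw) - 1) / fs
  # linear frequency sweep: phase = 2*pi*(f_lo*t + (f_hi - f_lo)*t^2 / (2*T))
  phase <- 2 * pi * (spec$sweep_f_lo * t_sw +
                       (spec$sweep_f_hi - spec$sweep_f_lo) * t_sw^2 / (2 * spec$sweep_s))
  sweep <- 0.5 * (1 + sin(phase))
  t_am <- (seq_len(n_am) - 1) / fs
  ramp <- t_am / spec$am_s
  am <- 0.5 * (1 + ramp * sin(2 * pi * spec$am_freq * t_am))
  x <- c(rep(1, n_on), rep(0, n_off), sweep, am)
  muerg_signal(x, fs, "chirp stimulus")
}

# Biphasic impulse response of the surrogate retina: a dominant slow lobe
# (~200 ms to peak, b-wave-like kinetics) followed by a slower opposing
# lobe with half the area. The sluggish kinetics make the deterministic
# response a smooth, stereotyped trace whose multiscale entropy at the
# complexity window sits well below pink noise's — the contrast the
# cohort's complexity dial relies on.
biphasic_kernel <- function(fs, tau1 = 0.2, tau2 = 0.4, w = 0.5, dur = 2) {
  t <- seq(0, dur, by = 1 / fs)
  k <- (t / tau1) * exp(1 - t / tau1) - w * (t / tau2) * exp(1 - t / tau2)
  k / sum(abs(k))
}

#' Generate a surrogate micro-ERG trial set
#'
#' Emulates the structure of a recorded retinal field-potential response:
#' each trial is a mixture of a deterministic, band-limited (<= 30 Hz)
#' linear response to the stimulus (the stimulus convolved with a biphasic
#' kernel, then low-pass filtered) and trial-independent pink noise, plus a
#' small white measurement noise. `snr_mix` sets the pink-noise share:
#' 0 gives an almost noiseless, stimulus-locked response (coherence ~1 in
#' the passband), 1 gives pure 1/f irregularity uncoupled from the
#' stimulus. Larger `snr_mix` therefore yields larger multiscale entropy at
#' large scales, which is how synthetic cohorts encode complexity
#' differences.
#'
#' @param stimulus A [muerg_signal()] sampled at the target analysis rate.
#' @param snr_mix Pink-noise mixing fraction in \[0, 1\].
#' @param seed Integer seed.
#' @param n_trials Number of repetitions (default 21, the recording
#'   protocol's repetition count).
#' @param white_sd Standard deviation of the additive measurement noise
#'   relative to the unit-variance components (default 0.02).
#' @param ... Metadata passed to [trialset()] (`protocol`, `subject`,
#'   `group`, `age`, `sex`).
#' @return A [trialset()] of `n_trials` x `length(stimulus)` samples.
#' @export
generate_surrogate_response <- function(stimulus, snr_mix, seed, n_trials = 21,
                                        white_sd = 0.02, ...) {
  if (!inherits(stimulus, "muerg_signal")) abort("`stimulus` must be a muerg_signal.")
  n <- length(stimulus)
  if (n < 1L) abort("`stimulus` must not be empty.")
  if (!is.numeric(snr_mix) || length(snr_mix) != 1L || snr_mix < 0 || snr_mix > 1) {
    abort("`snr_mix` must be a single value in [0, 1].")
  }
  fs <- stimulus$fs
  k <- biphasic_kernel(fs)
  det <- stats::filter(stimulus$samples - mean(stimulus$samples), k,
                       method = "convolution", sides = 1)
  det[is.na(det)] <- 0
  det <- lowpass_filter(as.double(det), fs, cutoff = 30, order = 4, zero_phase = TRUE)
  s <- sd(det)
  if (s > 0) det <- (det - mean(det)) / s
  trials <- withr::with_seed(seed, {
    t(vapply(seq_len(n_trials), function(i) {
      pink <- generate_pink_noise(max(n, 16L), seed = child_seed(seed, i), fs = fs)$samples[seq_len(n)]
      (1 - snr_mix) * det + snr_mix * pink + white_sd * rnorm(n)
    }, numeric(n)))
  })
  trialset(trials, fs = fs, ...)
}

#' Specify a synthetic cohort
#'
#' Describes a labelled multi-group cohort: each group has a size, a
#' complexity offset (the centre of its subjects' pink-noise share
#' `snr_mix`, so expected complexity index increases with the offset) and
#' a male fraction. Defaults emulate a four-group condition x age design
#' with 13/12/11/11 retinas and complexity decreasing from the
#' healthy-young to the disease-adult group.
#'
#' @param groups Data frame with columns `label`, `n_subjects`,
#'   `complexity_offset`, `sex_ratio` (male fraction).
#' @param n_trials Repetitions per subject (default 21).
#' @param fs_native Nominal acquisition rate carried as metadata (Hz).
#' @param fs_target Analysis sampling rate (Hz); surrogates are generated
#'   at this rate.
#' @param protocol `"NI"` (natural-like, default) or `"CS"` (chirp).
#' @param offset_sd Between-subject SD of `snr_mix` around the group
#'   offset (default 0.05).
#' @param seed Integer seed; cohort generation is a pure function of the
#'   spec.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_cohort_groups(), n_trials = 21,
                        fs_native = 20000, fs_target = 200,
                        protocol = c("NI", "CS"), offset_sd = 0.05, seed = 1) {
  protocol <- match.arg(protocol)
  groups <- as_tibble(groups)
  need <- c("label", "n_subjects", "complexity_offset", "sex_ratio")
  if (!all(need %in% names(groups))) {
    abort(sprintf("`groups` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(groups$label)) abort("Duplicate group labels are not allowed.")
  if (any(groups$n_subjects < 1)) abort("Each group needs at least one subject.")
  if (any(groups$complexity_offset < 0 | groups$complexity_offset > 1)) {
    abort("`complexity_offset` must lie in [0, 1].")
  }
  structure(list(groups = groups, n_trials = as.integer(n_trials),
                 fs_native = fs_native, fs_target = fs_target,
                 protocol = protocol, offset_sd = offset_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default four-group cohort design
#'
#' Healthy (WT-like) and disease-model (AD-like) groups at two age
#' classes, sized 13/12/11/11 with complexity offsets ordered to mirror a
#' complexity-loss-with-age-and-disease pattern, and male fractions taken
#' from a typical condition x age design.
#'
#' @return A tibble usable as the `groups` argument of [cohort_spec()].
#' @export
default_cohort_groups <- function() {
  tibble(
    label = c("WT-young", "AD-young", "WT-adult", "AD-adult"),
    n_subjects = c(13L, 12L, 11L, 11L),
    complexity_offset = c(0.70, 0.55, 0.50, 0.40),
    sex_ratio = c(9 / 13, 2 / 12, 5 / 11, 5 / 11)
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws, for each subject, a pink-noise share `snr_mix` around its
#' group's complexity offset (clamped to \[0.02, 0.98\]), a sex label from
#' the group's male fraction, and a surrogate trial set in response to a
#' single shared stimulus. Bit-identical reruns follow from the spec's
#' seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject`, `group`, `sex`,
#'   `snr_mix` and a `trials` list-column of [trialset()] objects. The
#'   shared stimulus is attached as attribute `"stimulus"`.
#' @examples
#' groups <- tibble::tibble(label = c("lo", "hi"), n_subjects = c(2, 2),
#'                          complexity_offset = c(0.2, 0.8), sex_ratio = 0.5)
#' cohort <- generate_cohort(cohort_spec(groups, seed = 42))
#' cohort
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  st_spec <- if (spec$protocol == "NI") {
    stimulus_spec("natural", fs = spec$fs_target)
  } else {
    stimulus_spec("chirp", fs = spec$fs_target)
  }
  stimulus <- generate_stimulus(st_spec, seed = child_seed(spec$seed, 0))
  g <- spec$groups
  rows <- withr::with_seed(spec$seed, {
    purrr::pmap(list(g$label, g$n_subjects, g$complexity_offset, g$sex_ratio, seq_len(nrow(g))),
                function(label, n_sub, offset, ratio, gi) {
      purrr::map(seq_len(n_sub), function(si) {
        snr <- min(max(offset + rnorm(1, 0, spec$offset_sd), 0.02), 0.98)
        sex <- if (rbinom(1, 1, ratio) == 1) "M" else "F"
        id <- sprintf("%s-%02d", label, si)
        ts <- generate_surrogate_response(
          stimulus, snr_mix = snr, seed = child_seed(spec$seed, gi * 1000L + si),
          n_trials = spec$n_trials, protocol = spec$protocol,
          subject = id, group = label, sex = sex
        )
        tibble(subject = id, group = label, sex = sex, snr_mix = snr,
               trials = list(ts))
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "stimulus") <- stimulus
  attr(out, "spec") <- spec
  out
}
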