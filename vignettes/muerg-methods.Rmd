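---
title: "Multiscale entropy analysis of retinal signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy analysis of retinal signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data generator does and does not
emulate, and where the genuinely open design choices were settled.

## The estimators

**Sample entropy.** For a series of length $N$, embed all $N-m$
templates of length $m$ and, for each, count the other templates within
Chebyshev distance $r$ (self-matches excluded). The statistic is
$\ln(\sum_i U_i^m / \sum_i U_i^{m+1})$, using the same $N-m$ templates at
both lengths. When no pair matches at length $m+1$ the ratio is
undefined; `sample_entropy()` returns a flagged `NA` rather than an
error, because the composite multiscale estimators must be able to
tabulate undefined scales across seeds.

**Fuzzy entropy.** The hard threshold is replaced by a membership
function of the distance. Two conventions are implemented behind
`membership_convention`: the default `gaussian_ratio`,
$\exp(-(d/r)^n)$, and `chen_original`, $\exp(-d^n/r)$, the form of the
original fuzzy-entropy literature. The default exponent is $n = 2$ (the
quadratic exponential). With `template_demean = TRUE` (default) each
template is centred on its own mean before the distance, which makes the
statistic exactly invariant to baseline shifts and — with $r$ expressed
as a fraction of the signal's SD — to positive rescaling; both
invariances are asserted in the test suite.

**Coarse-graining and the multiscale variants.** Scale $\tau$ replaces
the series by means of $\tau$ consecutive samples in non-overlapping
windows; there are $\tau$ possible window alignments. `mse_curve()`
offers the plain estimator (alignment 0 only), the composite (CMSE:
entropies of all alignments averaged; undefined if any alignment is
undefined) and the refined composite (RCMSE, default: match quantities
of all alignments summed at both template lengths, one logarithm at the
end). The refined form exists precisely to tame undefined estimates on
short coarse-grained series; the acceptance suite quantifies this
(hundreds of undefined CMSE scales versus a handful for RCMSE on
300-sample white noise at scales up to 50).

**The similarity threshold across scales.** $r$ is fixed once as
`r * sd` of the scale-1 analysis signal (population SD) and reused at
every scale. This is standard multiscale practice: coarse-graining
shrinks the variance of uncorrelated signals, and re-normalising $r$ per
scale would hide exactly the variance decay that distinguishes white
from 1/f noise. `r_scaling = "per_scale"` is available for cross-checks
against toolboxes that renormalise.

**The complexity index.** `complexity_index()` sums the curve over an
inclusive scale window, by default 20–44. At 200 Hz, scale 20 confines
the surviving content to roughly ≤ 10 Hz — the band retinal field
potentials respond in — and 44 is the largest scale at which a
2200-sample trace still leaves 50 coarse-grained samples, the shortest
series for which fuzzy entropy is considered consistent
(`tau_max = floor(N / min_series_length)`, i.e. $2200/50 = 44$). An
undefined value inside the window is an error naming the offending
scales, not a silent `NA` sum.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `m` | 2 | samples | short templates suit 2200-sample traces |
| `r` | 0.2 | × SD | common calibration; curves change smoothly in 0.1–0.5 |
| `fuzzy_exponent` | 2 | — | quadratic exponential membership |
| `template_demean` | on | — | baseline-shift invariance |
| `min_series_length` | 50 | samples | shortest reliable grain; sets `tau_max` |
| `scale_lo`, `scale_hi` | 20, 44 | scales | ≤ 10 Hz complexity window |
| `lp_cutoff` | 30 | Hz | µERG band; anti-alias for 200 Hz |
| `fs_target` | 200 | Hz | analysis rate |
| `window_size`, `overlap` | 256, 128 | samples | Welch resolution/variance trade-off |

## Preprocessing

Trials are averaged pointwise first; averaging and linear filtering
commute, so the order is a free choice and the cheaper one is taken
(averaging first filters one trace instead of 21). The low-pass is an
order-4 Butterworth applied forward–backward (`filtfilt`), i.e. zero
phase, so response latencies are not displaced; the filter family and
order are not dictated by the recording protocol and were chosen as the
standard for physiological traces. "Subsampling" is plain decimation
after the anti-alias filter; only integer decimation factors are
supported (the modelled acquisition chain is 20 kHz → 200 Hz, factor
100) and a non-integer ratio is an error rather than a silent resample.
Preprocessing is linear to numerical tolerance and leaves less than 1 %
of the output energy above 1.5 × the cutoff (both asserted in tests).

## The synthetic-data module

The generator produces everything the pipeline consumes, calibrated to
the recording protocol it stands in for: 21 repetitions per subject,
11 s natural-like traces of exactly 2200 samples at 200 Hz (the chirp
protocol: 3 s ON step, 3 s OFF, 1→10 Hz linear sweep, then an
amplitude-ramped 1 Hz sinusoid, ≈ 35 s in total), and labelled
multi-group cohorts.

**Noises.** Uniform noise on $[-1,1]$ is the simple reference; pink
noise is synthesized in the frequency domain (amplitudes
$\propto f^{-1/2}$, i.i.d. random phases, inverse transform, unit
variance) so its spectral exponent is exactly controllable — the Welch
log–log slope calibration (−1 ± 0.1) is part of the acceptance surface.
Amplitude normalisation is unit variance by convention; the scaling used
for the original noise illustrations is not documented anywhere, and
entropy with $r$ as a fraction of SD is scale-invariant anyway.

**Surrogate µERG responses.** Each trial is
$(1-s)\,d(t) + s\,p_i(t) + \varepsilon_i(t)$: a deterministic
band-limited response $d$ (the stimulus convolved with a biphasic
kernel, low-passed at 30 Hz, unit variance), trial-independent pink
noise $p_i$, and small white measurement noise
($\sigma = 0.02$). The mixing fraction $s$ (`snr_mix`) is the
complexity dial.

The kernel deserves a note, because its shape decides the *direction*
of that dial. A fast biphasic kernel (zero net area, tens of
milliseconds) spectrally whitens the 1/f natural-like stimulus, and a
band-limited broadband trace measures *more* irregular across the
complexity window than pink noise does — which would invert the
intended mapping. The package therefore uses slow, b-wave-like kinetics
(lobes peaking at 0.2 s and 0.4 s, opposing lobe half the area): the
deterministic response is then a smooth stereotyped trace whose
complexity index sits well below pink noise's, and the expected
complexity index increases monotonically in `snr_mix` — the property the
cohort recovery test exercises end to end.

**Cohorts.** Each group has a size, a `complexity_offset` (the centre of
its subjects' `snr_mix`, jittered with SD 0.05 and clamped to
$[0.02, 0.98]$) and a male fraction. The default four-group design —
13/12/11/11 subjects, offsets 0.70/0.55/0.50/0.40, condition × age
labels — emulates a complexity-loss-with-age-and-disease pattern at
realistic cohort sizes. Sex labels are generated but unused by the
default analyses: they enable sex-stratified summaries without
committing to any sex effect model. Cohort generation is a pure function
of its spec (bit-identical reruns, asserted in tests); all subject and
stimulus seeds derive from the one spec seed.

**What the generator does not emulate.** No photoreceptor biophysics, no
actual natural-image rendering, no electrode-level structure (the input
boundary is the channel-averaged trial matrix), no artifact or drift
processes, and no sex effect on complexity. Surrogates are generated
directly at the 200 Hz analysis rate — after a 30 Hz low-pass, nothing
distinguishes them from traces decimated from 20 kHz — so the native
acquisition rate is metadata only. Passing tests therefore demonstrate
that the *estimators and pipeline* behave as specified on signals with
the right second-order and multiscale structure, not that real retinas
behave like the surrogate model.

## Numerical choices

* Fuzzy memberships below $e^{-46} \approx 10^{-20}$ are truncated to
  zero in the compiled kernel; the induced error on any match sum is
  below $10^{-14}$, versus the $10^{-10}$ tolerance at which the
  estimators are held to brute-force references.
* A constant series has zero SD, hence $r = 0$; distances are all zero
  and the entropy is defined as 0 (both estimators), rather than a 0/0.
* Welch segments are constant-detrended and Hann-windowed (periodic
  window), one-sided density scaling; coherence is computed from the raw
  averaged cross- and auto-spectra on the same segmentation and clipped
  to $[0,1]$ against floating-point excursions. A single segment would
  make coherence identically 1, so fewer than two segments is an error.
* Mann–Whitney: exact null when both groups have ≤ 12 observations and
  there are no ties, otherwise the normal approximation with continuity
  and tie correction. The threshold keeps the exact path feasible while
  covering the cohort sizes of interest; the exact branch is held to a
  full enumeration oracle in tests. If every value in both groups is
  identical the test is degenerate: warning, $p = 1$, $U = n_a n_b / 2$.
* Quartiles use linear interpolation between order statistics
  (`quantile` type 7), the common default; the convention used for the
  original tables is undocumented, so exact quartile reproduction may
  depend on it.
* Pairwise group comparisons are reported unadjusted (matching the
  analysis convention the package reproduces), with a clearly separate
  Holm-adjusted column for users who want family-wise control.

## Simulation sizes

The test and acceptance simulations use the package's native signal geometry
(N = 2200, m = 2, r = 0.2, scales to 44; cohorts of 12–13 subjects per
group with 21 trials each). Replicate counts were sized for stable
pass/fail decisions at desk scale: 20 seeds for the noise-shape checks,
100 seeds for undefined-scale tabulation, 1000 null simulations for the
type-I rate, and 200 pipeline replicates for the two-group power check
(the power simulations evaluate the curve on the complexity window
20–44 only, which is sufficient for the index and an order of magnitude
cheaper than the full curve).

## Known limitations and honest failures

* **Flat pink-noise curves.** Exactly-1/f noise is self-similar, so its
  RCMSE curve is theoretically flat across scales. The package's curves
  reproduce the rise below scale ~10 that the 30 Hz low-pass induces,
  and pink noise holds its entropy far above white noise's at large
  scales; but a strictly non-decreasing trend over scales 10–44 is a
  coin flip seed by seed (the scale-40 minus scale-10 difference is
  ~0.001 ± 0.05 nats). The acceptance suite states the stronger
  monotone-increase expectation for pink noise and fails it, by design —
  the assertion documents the discrepancy rather than papering over it.
* **Band-limited white noise is not low-entropy at small scales.** The
  "entropy ≈ 0 below scale ⌈200/30⌉ = 7" argument holds for retinal
  traces, whose power sits well below the cutoff (the µERG surrogate's
  scale-1 entropy is ≈ 0.1 nats); white noise filling the whole 0–30 Hz
  band keeps adjacent-sample differences of ~0.5 SD and measures 1–2
  nats at scales 1–6. The corresponding acceptance assertion fails and
  is kept as the record of that analysis.
* Real-data reproduction of the published complexity tables requires the
  archived recordings and knowledge of the exact toolbox conventions
  (membership form, per-scale r handling, demeaning); all three are
  exposed as switches, but no downloader or deposit adapter is shipped.
* The complexity window 20–44 is tuned to 2200-sample, 200 Hz traces;
  for other geometries the window should be re-derived from the
  frequency argument, not reused verbatim.
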