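#' Coarse-grain a time series
#'
#' Reduces a series at scale `tau` by averaging `tau` consecutive samples in
#' non-overlapping windows; the scale-`tau` grain of an `N`-sample series has
#' `floor((N - offset) / tau)` samples. `offset` selects which of the `tau`
#' possible window alignments is used (0 = the conventional grain starting
#' at the first sample), the ingredient the composite multiscale variants
#' average over.
#'
#' @param x Numeric vector or [muerg_signal()].
#' @param tau Integer scale >= 1 (window length in samples).
#' @param offset Integer in `0..tau-1`: index of the first sample of the
#'   first window.
#' @return Numeric vector of window means.
#' @examples
#' coarse_grain(1:6, 2)      # 1.5 3.5 5.5
#' coarse_grain(1:5, 2, 1)   # 2.5 4.5
#' @export
coarse_grain <- function(x, tau, offset = 0) {
  x <- as_samples(x)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) abort("`tau` must be a positive integer.")
  if (tau > length(x)) abort(sprintf("`tau` (%d) exceeds the series length (%d).", tau, length(x)))
  offset <- as.integer(offset)
  if (is.na(offset) || offset < 0L || offset >= tau) {
    abort(sprintf("`offset` must lie in 0..%d.", tau - 1L))
  }
  if (tau == 1L) return(x)
  L <- (length(x) - offset) %/% tau
  if (L < 1L) abort("Series too short for this scale/offset combination.")
  colMeans(matrix(x[offset + seq_len(L * tau)], nrow = tau))
}

#' Fuzzy similarity membership
#'
#' Continuous degree of similarity assigned to a template distance `d`
#' under threshold `r`. Two conventions are provided:
#' `"gaussian_ratio"` (default) gives `exp(-(d/r)^n)`; `"chen_original"`
#' gives `exp(-d^n / r)`, the form of the original fuzzy-entropy
#' literature. Both are 1 at zero distance and decay monotonically.
#'
#' @param d Non-negative distance(s).
#' @param r Positive similarity threshold (same units as `d`).
#' @param exponent Positive exponent `n` (default 2, the quadratic
#'   exponential).
#' @param convention `"gaussian_ratio"` or `"chen_original"`.
#' @return Membership value(s) in `(0, 1]`.
#' @examples
#' fuzzy_membership(0, r = 0.2)               # 1
#' fuzzy_membership(0.2, r = 0.2)             # exp(-1)
#' @export
fuzzy_membership <- function(d, r, exponent = 2,
                             convention = c("gaussian_ratio", "chen_original")) {
  convention <- match.arg(convention)
  if (any(d < 0)) abort("`d` must be non-negative.")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) abort("`r` must be a single positive number.")
  if (exponent <= 0) abort("`exponent` must be positive.")
  if (convention == "gaussian_ratio") exp(-(d / r)^exponent) else exp(-d^exponent / r)
}

#' Entropy parameter bundle
#'
#' Collects the parameters shared by [sample_entropy()], [fuzzy_entropy()]
#' and [mse_curve()]. Defaults follow common practice for short
#' physiological series: template length `m` = 2 and threshold `r` = 0.2
#' standard deviations; fuzzy entropy is quoted as consistent for series of
#' 50 samples or more, which is where `min_length` comes from.
#'
#' @param m Embedding (template) length, >= 1.
#' @param r Similarity threshold as a fraction of the scale-1 signal's
#'   (population) standard deviation.
#' @param exponent Fuzzy membership exponent (default 2).
#' @param convention Fuzzy membership convention, see [fuzzy_membership()].
#' @param demean Should each template be centred on its own mean before the
#'   Chebyshev distance (fuzzy entropy only)? Default `TRUE`.
#' @param min_length Shortest series length considered reliable; shorter
#'   inputs trigger a warning, not an error.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r = 0.2, exponent = 2,
                           convention = c("gaussian_ratio", "chen_original"),
                           demean = TRUE, min_length = 50) {
  convention <- match.arg(convention)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) abort("`m` must be a positive integer.")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) abort("`r` must be a single positive number.")
  if (exponent <= 0) abort("`exponent` must be positive.")
  structure(list(m = m, r = r, exponent = exponent, convention = convention,
                 demean = isTRUE(demean), min_length = as.integer(min_length)),
            class = "entropy_params")
}

# shared validation for the two entropy estimators
check_entropy_input <- function(x, m, min_length, warn_short = TRUE) {
  if (m >= length(x)) {
    abort(sprintf("Template length m = %d requires a series longer than m (got %d samples).",
                  m, length(x)))
  }
  if (warn_short && length(x) < min_length) {
    warn(sprintf("Series of %d samples is below the recommended minimum of %d; the estimate may be unreliable.",
                 length(x), min_length))
  }
  invisible(TRUE)
}

#' Sample entropy
#'
#' Regularity statistic of a time series: the negative logarithm of the
#' conditional probability that two templates matching within `r` at length
#' `m` (Chebyshev distance, self-matches excluded) still match at length
#' `m + 1`. Computed as `ln(sum_i U_i^m / sum_i U_i^{m+1})` over the
#' `N - m` templates used at both lengths. When no template pair matches at
#' length `m + 1` the statistic is undefined and `NA` is returned (a
#' flagged value, not an error), which is what the composite multiscale
#' variants must be able to average over.
#'
#' @inheritParams coarse_grain
#' @param m Template length.
#' @param r Similarity threshold as a fraction of the series' population
#'   standard deviation (override with `r_absolute`).
#' @param min_length Warn below this length (see [entropy_params()]).
#' @param r_absolute Optional absolute threshold in signal units; when
#'   given, `r` is ignored. Used by [mse_curve()] to hold `r` fixed at the
#'   scale-1 value across scales.
#' @return Entropy in nats, or `NA` when undefined.
#' @examples
#' sample_entropy(rep(1, 100))                       # 0: perfectly regular
#' sample_entropy(generate_uniform_noise(300, 1))    # irregular, > 1
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, min_length = 50, r_absolute = NULL) {
  x <- as_samples(x)
  m <- as.integer(m)
  check_entropy_input(x, m, min_length)
  r_abs <- if (is.null(r_absolute)) r * sd_pop(x) else as.double(r_absolute)
  s <- entropy_sums_cpp(x, m, r_abs, FALSE, 2, 0L, FALSE)
  if (s[2] == 0) return(NA_real_)
  log(s[1] / s[2])
}

#' Fuzzy entropy
#'
#' Sample entropy with the hard match threshold replaced by a continuous
#' membership function of the inter-template Chebyshev distance
#' ([fuzzy_membership()]). With `demean = TRUE` (default) each template is
#' centred on its own mean first, making the statistic invariant to
#' baseline shifts. Memberships are strictly positive, so fuzzy entropy is
#' defined wherever the sums do not underflow.
#'
#' @inheritParams sample_entropy
#' @param exponent,convention,demean See [entropy_params()].
#' @return Entropy in nats (`NA` only on numerical underflow of the match
#'   sums).
#' @examples
#' fuzzy_entropy(rep(2, 100))                        # 0
#' fuzzy_entropy(generate_uniform_noise(300, 1))
#' @export
fuzzy_entropy <- function(x, m = 2, r = 0.2, exponent = 2,
                          convention = c("gaussian_ratio", "chen_original"),
                          demean = TRUE, min_length = 50, r_absolute = NULL) {
  convention <- match.arg(convention)
  x <- as_samples(x)
  m <- as.integer(m)
  check_entropy_input(x, m, min_length)
  r_abs <- if (is.null(r_absolute)) r * sd_pop(x) else as.double(r_absolute)
  s <- entropy_sums_cpp(x, m, r_abs, TRUE, exponent,
                        if (convention == "gaussian_ratio") 0L else 1L, isTRUE(demean))
  if (s[2] == 0) return(NA_real_)
  log(s[1] / s[2])
}

#' Multiscale entropy curve
#'
#' Computes an entropy-versus-scale curve by coarse-graining the series at
#' each scale and applying sample or fuzzy entropy. Three estimators are
#' available:
#'
#' * `"mse"` — entropy of the single conventional (offset 0) grain;
#' * `"cmse"` — composite: entropies of all `tau` offset grains averaged
#'   (undefined at a scale if any grain is undefined);
#' * `"rcmse"` — refined composite (default): the match quantities of all
#'   `tau` grains are summed at lengths `m` and `m + 1` and a single
#'   logarithm of the summed ratio is taken, which markedly reduces the
#'   chance of an undefined value on short series.
#'
#' The similarity threshold is fixed once from the scale-1 series'
#' population standard deviation and reused at every scale (standard
#' multiscale practice, preventing entropy inflation as coarse-graining
#' shrinks the variance); set `r_scaling = "per_scale"` to recompute it per
#' grain for cross-checks against toolboxes that do so.
#'
#' The default maximum scale follows the rule `floor(N / min_length)`, e.g.
#' 2200 samples / 50 = scale 44.
#'
#' @inheritParams fuzzy_entropy
#' @param tau_max Largest scale; default `floor(length(x) / min_length)`.
#' @param scales Integer vector of scales to evaluate (default
#'   `1:tau_max`); evaluating only the scales of interest (e.g. the
#'   complexity window) saves substantial time.
#' @param method `"rcmse"`, `"cmse"` or `"mse"`.
#' @param entropy Base entropy: `"fuzzy"` or `"sample"`.
#' @param r_scaling `"global"` (threshold from the scale-1 SD, default) or
#'   `"per_scale"`.
#' @return A tibble of class `mse_curve` with columns `scale`, `entropy`
#'   (nats; `NA` where undefined) and `defined`; parameters are attached as
#'   attributes.
#' @examples
#' x <- generate_pink_noise(2200, seed = 7)
#' curve <- mse_curve(x, tau_max = 44)
#' head(curve)
#' @export
mse_curve <- function(x, m = 2, r = 0.2, tau_max = NULL, scales = NULL,
                      method = c("rcmse", "cmse", "mse"),
                      entropy = c("fuzzy", "sample"),
                      exponent = 2,
                      convention = c("gaussian_ratio", "chen_original"),
                      demean = TRUE, min_length = 50,
                      r_scaling = c("global", "per_scale")) {
  method <- match.arg(method)
  entropy <- match.arg(entropy)
  convention <- match.arg(convention)
  r_scaling <- match.arg(r_scaling)
  x <- as_samples(x)
  N <- length(x)
  m <- as.integer(m)
  if (m >= N) abort("Series shorter than the template length.")
  if (is.null(tau_max)) tau_max <- max(1L, N %/% as.integer(min_length))
  tau_max <- as.integer(tau_max)
  if (tau_max < 1L) abort("`tau_max` must be >= 1.")
  if (is.null(scales)) scales <- seq_len(tau_max)
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < 1L)) abort("`scales` must be positive integers.")
  if (max(scales) > N %/% (m + 1L)) {
    abort("Largest scale leaves fewer samples than one template.")
  }
  if (N %/% max(scales) < min_length) {
    warn(sprintf("Coarse-grained length at scale %d is %d samples, below the recommended minimum of %d.",
                 max(scales), N %/% max(scales), min_length))
  }

  fuzzy <- entropy == "fuzzy"
  conv <- if (convention == "gaussian_ratio") 0L else 1L
  r_global <- r * sd_pop(x)

  ent <- vapply(scales, function(tau) {
    r_abs <- if (r_scaling == "global") r_global else {
      r * sd_pop(coarse_grain(x, tau))
    }
    if (method == "mse") {
      s <- entropy_sums_cpp(coarse_grain(x, tau), m, r_abs, fuzzy, exponent, conv, demean)
      if (s[2] == 0) NA_real_ else log(s[1] / s[2])
    } else {
      sums <- mse_sums_cpp(x, tau, m, r_abs, fuzzy, exponent, conv, demean)
      if (method == "cmse") {
        if (any(sums[2, ] == 0)) NA_real_ else mean(log(sums[1, ] / sums[2, ]))
      } else {
        A <- sum(sums[1, ]); B <- sum(sums[2, ])
        if (B == 0) NA_real_ else log(A / B)
      }
    }
  }, numeric(1))

  out <- tibble(scale = scales, entropy = ent, defined = !is.na(ent))
  class(out) <- c("mse_curve", class(out))
  attr(out, "params") <- list(m = m, r = r, exponent = exponent,
                              convention = convention, demean = demean,
                              method = method, entropy = entropy,
                              r_scaling = r_scaling, n = N)
  out
}

#' Complexity index of a multiscale entropy curve
#'
#' Cumulative entropy (area under the multiscale entropy curve, unit scale
#' step) over an inclusive scale window, by default scales 20-44: at a 200
#' Hz sampling rate, scale 20 and above confines the contributing
#' frequency content to <= 10 Hz, the band retinal field potentials
#' respond in.
#'
#' @param curve An [mse_curve()] (or any data frame with `scale` and
#'   `entropy` columns).
#' @param scale_lo,scale_hi Inclusive window endpoints (defaults 20 and 44).
#' @return A one-row tibble with `index` (nats), `scale_lo`, `scale_hi`,
#'   `n_scales`.
#' @examples
#' curve <- tibble::tibble(scale = 1:44, entropy = rep(1, 44))
#' complexity_index(curve)$index   # 25 scales x 1 nat
#' @export
complexity_index <- function(curve, scale_lo = 20, scale_hi = 44) {
  if (!is.data.frame(curve) || !all(c("scale", "entropy") %in% names(curve))) {
    abort("`curve` must have `scale` and `entropy` columns.")
  }
  scale_lo <- as.integer(scale_lo)
  scale_hi <- as.integer(scale_hi)
  if (scale_lo > scale_hi) abort("`scale_lo` must not exceed `scale_hi`.")
  window <- seq.int(scale_lo, scale_hi)
  missing_scales <- setdiff(window, curve$scale)
  if (length(missing_scales)) {
    abort(sprintf("Curve lacks scales %s required by the window %d-%d.",
                  paste(missing_scales, collapse = ", "), scale_lo, scale_hi))
  }
  vals <- curve$entropy[match(window, curve$scale)]
  if (anyNA(vals)) {
    abort(sprintf("Entropy is undefined at scale(s) %s inside the window %d-%d.",
                  paste(window[is.na(vals)], collapse = ", "), scale_lo, scale_hi))
  }
  tibble(index = sum(vals), scale_lo = scale_lo, scale_hi = scale_hi,
         n_scales = length(window))
}
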