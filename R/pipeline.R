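#' Configure an end-to-end analysis run
#'
#' Bundles every stage's parameters: the cohort to analyse (a
#' [cohort_spec()] to simulate, or an already generated cohort tibble, or
#' a character vector of trial-set file paths), preprocessing, entropy
#' estimation, the complexity window, Welch parameters and output
#' handling. All downstream preconditions are checked here so a run fails
#' at configuration time, not mid-pipeline.
#'
#' @param cohort [cohort_spec()], cohort tibble from [generate_cohort()],
#'   or character vector of paths readable by [read_trialset()].
#' @param preprocess A [preprocess_config()].
#' @param entropy An [entropy_params()].
#' @param method,base_entropy Multiscale estimator and base entropy
#'   (defaults `"rcmse"` + `"fuzzy"`, see [mse_curve()]).
#' @param tau_max Largest scale; `NULL` applies the
#'   `floor(N / min_length)` rule to the analysis length.
#' @param scales Scales at which to evaluate the curve (default
#'   `1:tau_max`; restrict to the complexity window for speed in large
#'   simulations).
#' @param scale_lo,scale_hi Complexity window (defaults 20-44).
#' @param target_length Analysis length in samples after preprocessing
#'   (default 2200, the 11 s natural-image trace at 200 Hz); longer
#'   traces are truncated, and `NULL` keeps full length.
#' @param window_size,overlap Welch parameters for the spectral panel.
#' @param out_dir Optional output directory for [write_results()] and the
#'   run manifest.
#' @param seed Integer seed governing every stochastic stage; `NULL`
#'   (default) defers to the cohort spec's own seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       preprocess = preprocess_config(),
                       entropy = entropy_params(),
                       method = c("rcmse", "cmse", "mse"),
                       base_entropy = c("fuzzy", "sample"),
                       tau_max = NULL, scales = NULL,
                       scale_lo = 20, scale_hi = 44,
                       target_length = 2200,
                       window_size = 256, overlap = 128,
                       out_dir = NULL, seed = NULL) {
  method <- match.arg(method)
  base_entropy <- match.arg(base_entropy)
  ok_cohort <- inherits(cohort, "cohort_spec") ||
    (is.data.frame(cohort) && "trials" %in% names(cohort)) ||
    is.character(cohort)
  if (!ok_cohort) abort("`cohort` must be a cohort_spec, a generated cohort, or file paths.")
  if (!inherits(preprocess, "preprocess_config")) abort("`preprocess` must be a preprocess_config.")
  if (!inherits(entropy, "entropy_params")) abort("`entropy` must be entropy_params.")
  scale_lo <- as.integer(scale_lo)
  scale_hi <- as.integer(scale_hi)
  if (scale_lo < 1L || scale_lo > scale_hi) abort("Need 1 <= scale_lo <= scale_hi.")
  if (!is.null(tau_max) && tau_max < scale_hi) {
    abort("`tau_max` must reach the top of the complexity window.")
  }
  if (!is.null(scales) && !all(seq.int(scale_lo, scale_hi) %in% scales)) {
    abort("`scales` must contain the whole complexity window.")
  }
  if (overlap >= window_size) abort("`overlap` must be smaller than `window_size`.")
  structure(list(cohort = cohort, preprocess = preprocess, entropy = entropy,
                 method = method, base_entropy = base_entropy,
                 tau_max = tau_max, scales = scales,
                 scale_lo = scale_lo, scale_hi = scale_hi,
                 target_length = target_length,
                 window_size = as.integer(window_size),
                 overlap = as.integer(overlap),
                 out_dir = out_dir,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

# preprocess one subject's trial set to the analysis-ready signal
preprocess_subject <- function(ts, cfg) {
  s <- average_trials(ts)
  s <- lowpass_resample(s, cfg$preprocess)
  if (!is.null(cfg$target_length) && length(s$samples) > cfg$target_length) {
    s <- segment_to_length(s, cfg$target_length)
  }
  s
}

#' Run the full complexity analysis pipeline
#'
#' For each subject: average the repeated trials, low-pass filter and
#' decimate, truncate to the analysis length, compute the multiscale
#' entropy curve and the complexity index over the configured window;
#' then summarize groups and run all pairwise Mann-Whitney comparisons.
#' A Welch PSD per subject and (when the cohort carries its stimulus) the
#' stimulus-response coherence are computed for the spectral report.
#' Identical configurations produce bit-identical results.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress per-subject progress messages (default `TRUE`).
#' @return An object of class `muerg_analysis`: a list with tibbles
#'   `curves` (subject, group, sex, protocol, scale, entropy),
#'   `complexity` (subject, group, sex, protocol, snr_mix if synthetic,
#'   index), `stats` (pairwise comparisons), `summary` (per-group
#'   median/quartiles), `psd`, `coherence` (possibly `NULL`) and the
#'   `config`. Written to `cfg$out_dir` when set, together with a
#'   `manifest.txt` recording every parameter and seed.
#' @examples
#' \donttest{
#' groups <- tibble::tibble(label = c("lo", "hi"), n_subjects = 3,
#'                          complexity_offset = c(0.2, 0.8), sex_ratio = 0.5)
#' cfg <- run_config(cohort_spec(groups, seed = 7), scales = 20:44)
#' res <- run_pipeline(cfg)
#' tidy(res)
#' }
#' @export
run_pipeline <- function(cfg = run_config(), quiet = TRUE) {
  if (!inherits(cfg, "run_config")) abort("`cfg` must be a run_config.")
  cohort <- cfg$cohort
  if (inherits(cohort, "cohort_spec")) {
    if (!is.null(cfg$seed)) cohort$seed <- cfg$seed
    cohort <- generate_cohort(cohort)
  } else if (is.character(cohort)) {
    cohort <- purrr::map(cohort, read_trialset)
    cohort <- tibble(
      subject = purrr::map_chr(cohort, function(ts) if (nzchar(ts$subject)) ts$subject else basename(tempfile("s"))),
      group = purrr::map_chr(cohort, "group"),
      sex = purrr::map_chr(cohort, "sex"),
      snr_mix = NA_real_,
      trials = cohort
    )
  }
  stimulus <- attr(cohort, "stimulus")

  one_subject <- function(subject, group, sex, snr_mix, ts) {
    s <- tryCatch(preprocess_subject(ts, cfg), error = function(e) {
      abort(sprintf("Subject %s (%s): %s", subject, ts$protocol, conditionMessage(e)))
    })
    n <- length(s$samples)
    tau_max <- if (!is.null(cfg$tau_max)) cfg$tau_max else {
      max(cfg$scale_hi, n %/% cfg$entropy$min_length)
    }
    curve <- suppressWarnings(mse_curve(
      s, m = cfg$entropy$m, r = cfg$entropy$r, tau_max = tau_max,
      scales = cfg$scales, method = cfg$method, entropy = cfg$base_entropy,
      exponent = cfg$entropy$exponent, convention = cfg$entropy$convention,
      demean = cfg$entropy$demean, min_length = cfg$entropy$min_length
    ))
    ci <- tryCatch(complexity_index(curve, cfg$scale_lo, cfg$scale_hi),
                   error = function(e) {
                     abort(sprintf("Subject %s (%s): %s", subject, ts$protocol, conditionMessage(e)))
                   })
    psd <- welch_psd(s, cfg$window_size, cfg$overlap)
    coh <- NULL
    if (!is.null(stimulus) && length(stimulus$samples) == n && stimulus$fs == s$fs) {
      coh <- coherence(stimulus, s, cfg$window_size, cfg$overlap)
    }
    if (!quiet) {
      message(sprintf("[%s] protocol=%s n=%d scales=%d-%d index=%.4f",
                      subject, ts$protocol, n, cfg$scale_lo, cfg$scale_hi, ci$index))
    }
    list(
      curve = dplyr::bind_cols(tibble(subject = subject, group = group, sex = sex,
                                      protocol = ts$protocol), curve),
      complexity = tibble(subject = subject, group = group, sex = sex,
                          protocol = ts$protocol, snr_mix = snr_mix,
                          index = ci$index),
      psd = dplyr::bind_cols(tibble(subject = subject, group = group), psd),
      coh = if (!is.null(coh)) dplyr::bind_cols(tibble(subject = subject, group = group), coh)
    )
  }

  parts <- purrr::pmap(cohort[c("subject", "group", "sex", "snr_mix", "trials")],
                       function(subject, group, sex, snr_mix, trials) {
                         one_subject(subject, group, sex, snr_mix, trials)
                       })
  curves <- dplyr::bind_rows(purrr::map(parts, "curve"))
  complexity <- dplyr::bind_rows(purrr::map(parts, "complexity"))
  psd <- dplyr::bind_rows(purrr::map(parts, "psd"))
  coh <- dplyr::bind_rows(purrr::compact(purrr::map(parts, "coh")))
  if (nrow(coh) == 0) coh <- NULL
  stats <- if (length(unique(complexity$group)) >= 2) {
    compare_all_pairs(complexity)
  } else {
    NULL
  }
  res <- structure(list(curves = curves, complexity = complexity,
                        stats = stats, summary = summarize_groups(complexity),
                        psd = psd, coherence = coh, config = cfg),
                   class = "muerg_analysis")
  if (!is.null(cfg$out_dir)) {
    write_results(curves, complexity, cfg$out_dir, stats = stats)
    write_manifest(cfg, file.path(cfg$out_dir, "manifest.txt"))
  }
  res
}

# flat key=value record of every parameter and seed of a run
write_manifest <- function(cfg, path) {
  kv <- c(
    method = cfg$method, base_entropy = cfg$base_entropy,
    m = cfg$entropy$m, r = cfg$entropy$r,
    fuzzy_exponent = cfg$entropy$exponent,
    membership_convention = cfg$entropy$convention,
    template_demean = cfg$entropy$demean,
    min_series_length = cfg$entropy$min_length,
    lp_cutoff_hz = cfg$preprocess$lp_cutoff,
    fs_target_hz = cfg$preprocess$fs_target,
    filter_order = cfg$preprocess$filter_order,
    zero_phase = cfg$preprocess$zero_phase,
    tau_max = if (is.null(cfg$tau_max)) "auto" else cfg$tau_max,
    scale_lo = cfg$scale_lo, scale_hi = cfg$scale_hi,
    target_length = if (is.null(cfg$target_length)) "full" else cfg$target_length,
    window_size = cfg$window_size, overlap = cfg$overlap,
    seed = if (is.null(cfg$seed)) {
      if (inherits(cfg$cohort, "cohort_spec")) cfg$cohort$seed else "none"
    } else {
      cfg$seed
    }
  )
  writeLines(sprintf("%s=%s", names(kv), unname(kv)), path)
  invisible(path)
}

#' @export
print.muerg_analysis <- function(x, ...) {
  cat(sprintf("<muerg_analysis> %d subjects, %d group(s), %s/%s, complexity window %d-%d\n",
              nrow(x$complexity), length(unique(x$complexity$group)),
              toupper(x$config$method), x$config$base_entropy,
              x$config$scale_lo, x$config$scale_hi))
  print(x$summary)
  invisible(x)
}

#' Tidy the pairwise comparisons of an analysis
#'
#' @param x A `muerg_analysis` from [run_pipeline()].
#' @param ... Unused.
#' @return The pairwise Mann-Whitney table (one row per group pair), or
#'   the complexity table when only one group was analysed.
#' @method tidy muerg_analysis
#' @export
tidy.muerg_analysis <- function(x, ...) {
  if (!is.null(x$stats)) x$stats else x$complexity
}

#' One-row summary of an analysis
#'
#' @inheritParams tidy.muerg_analysis
#' @return A one-row tibble: subject/group counts, protocol(s), overall
#'   median complexity, number of significant pairs at the configured
#'   alpha.
#' @method glance muerg_analysis
#' @export
glance.muerg_analysis <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$complexity),
    n_groups = length(unique(x$complexity$group)),
    protocols = paste(unique(x$complexity$protocol), collapse = "+"),
    median_complexity = median(x$complexity$index),
    n_comparisons = if (is.null(x$stats)) 0L else nrow(x$stats),
    n_significant = if (is.null(x$stats)) 0L else sum(x$stats$significant)
  )
}
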