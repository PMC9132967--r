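#' Construct a sampled signal
#'
#' A `muerg_signal` is the unit every entropy and spectral operation
#' consumes: one uniformly sampled trace with its sampling rate and a free
#' text label. Most functions in the package also accept a bare numeric
#' vector wherever a signal is expected (supplying `fs` separately when the
#' operation needs it).
#'
#' @param samples Numeric vector of finite sample values (arbitrary units).
#' @param fs Sampling rate in Hz (> 0).
#' @param label Free-text label carried through analyses.
#' @return An object of class `muerg_signal`: a list with elements
#'   `samples`, `fs` and `label`.
#' @examples
#' s <- muerg_signal(sin(2 * pi * 2 * seq(0, 1, by = 1 / 200)), fs = 200)
#' s
#' @export
muerg_signal <- function(samples, fs, label = "") {
  samples <- as.double(samples)
  if (length(samples) < 1L) abort("`samples` must contain at least one value.")
  if (!all(is.finite(samples))) {
    abort(sprintf("`samples` contains %d non-finite value(s).", sum(!is.finite(samples))))
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  structure(list(samples = samples, fs = as.double(fs), label = as.character(label)[1]),
            class = "muerg_signal")
}

#' @export
print.muerg_signal <- function(x, ...) {
  cat(sprintf("<muerg_signal> %d samples @ %g Hz (%.4g s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' @export
length.muerg_signal <- function(x) length(x$samples)

#' @export
as.double.muerg_signal <- function(x, ...) x$samples

# resolve samples from a signal or numeric vector
as_samples <- function(x, arg = "x") {
  if (inherits(x, "muerg_signal")) return(x$samples)
  if (is.numeric(x)) return(as.double(x))
  abort(sprintf("`%s` must be a muerg_signal or a numeric vector.", arg))
}

# resolve a sampling rate, preferring an explicit fs over the signal's
resolve_fs <- function(x, fs = NULL, required = TRUE) {
  if (!is.null(fs)) return(as.double(fs))
  if (inherits(x, "muerg_signal")) return(x$fs)
  if (required) abort("Supply `fs` when the input is a bare numeric vector.")
  NA_real_
}

#' Construct a trial set
#'
#' A trial set holds the repeated responses of one retina (or one synthetic
#' subject) to a stimulation protocol: an `n_trials x n_samples` matrix at a
#' common sampling rate, plus subject metadata. The recordings the package
#' emulates used 21 repetitions per protocol.
#'
#' @param trials Numeric matrix, one row per repetition.
#' @param fs Sampling rate in Hz.
#' @param protocol Protocol label, `"CS"` (chirp stimulus) or `"NI"`
#'   (natural image) by convention; free text accepted.
#' @param subject,group,age,sex Optional metadata strings.
#' @return An object of class `trialset`.
#' @examples
#' ts <- trialset(matrix(rnorm(3 * 100), nrow = 3), fs = 200, protocol = "NI")
#' ts
#' @export
trialset <- function(trials, fs, protocol = "NI",
                     subject = "", group = "", age = "", sex = "") {
  trials <- as.matrix(trials)
  storage.mode(trials) <- "double"
  if (nrow(trials) < 1L) abort("A trial set needs at least one trial.")
  if (!all(is.finite(trials))) {
    bad <- which(!is.finite(trials), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite value at trial %d, sample %d.", bad[1], bad[2]))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) abort("`fs` must be a single positive number (Hz).")
  structure(list(trials = trials, fs = as.double(fs), protocol = as.character(protocol)[1],
                 subject = as.character(subject)[1], group = as.character(group)[1],
                 age = as.character(age)[1], sex = as.character(sex)[1]),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  cat(sprintf("<trialset> %d trials x %d samples @ %g Hz, protocol %s\n",
              nrow(x$trials), ncol(x$trials), x$fs, x$protocol))
  meta <- c(subject = x$subject, group = x$group, age = x$age, sex = x$sex)
  meta <- meta[nzchar(meta)]
  if (length(meta)) cat("  ", paste(names(meta), meta, sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.trialset <- function(x) dim(x$trials)

#' Tidy a trial set into long format
#'
#' @param x A [trialset()].
#' @param ... Unused.
#' @return A tibble with columns `trial`, `time` (s), `value`.
#' @method as_tibble trialset
#' @export
as_tibble.trialset <- function(x, ...) {
  n <- ncol(x$trials)
  tibble(
    trial = rep(seq_len(nrow(x$trials)), each = n),
    time = rep((seq_len(n) - 1) / x$fs, nrow(x$trials)),
    value = as.vector(t(x$trials))
  )
}
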