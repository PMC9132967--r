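# Interchange dialect: comma-separated values, '.' decimal point, UTF-8,
# with '#'-prefixed key=value metadata lines before the header row.

write_meta_lines <- function(con, meta) {
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
}

read_meta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([^=]+)=(.*)$", meta_lines))
  kv <- kv[lengths(kv) == 3]
  stats::setNames(vapply(kv, `[`, "", 3), trimws(vapply(kv, `[`, "", 2)))
}

#' Write a trial set to delimited text
#'
#' One column per trial, one row per sample, preceded by `#`-prefixed
#' metadata lines (`fs`, `protocol`, subject labels). The format
#' round-trips exactly through [read_trialset()] to 15 significant
#' digits.
#'
#' @param t A [trialset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trialset <- function(t, path) {
  if (!inherits(t, "trialset")) abort("`t` must be a trialset.")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write_meta_lines(con, c(fs = format(t$fs, digits = 15), protocol = t$protocol,
                          subject = t$subject, group = t$group,
                          age = t$age, sex = t$sex))
  df <- as.data.frame(t(t$trials))
  names(df) <- sprintf("trial_%d", seq_len(nrow(t$trials)))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, format, digits = 15, trim = TRUE,
                                     scientific = FALSE), sep = ",")), con)
  invisible(path)
}

#' Read a trial set from delimited text
#'
#' Parses the format written by [write_trialset()]: `#`-metadata lines
#' (at minimum `fs`; `protocol` and labels as available) followed by a
#' CSV matrix with one column per trial. Ragged rows, a missing sampling
#' rate, and non-finite entries are format/data errors (the latter
#' reported with its row and column).
#'
#' @param path File path.
#' @return A [trialset()].
#' @export
read_trialset <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  meta <- read_meta_lines(path)
  if (!"fs" %in% names(meta) || !is.finite(suppressWarnings(as.numeric(meta[["fs"]])))) {
    abort(sprintf("Format error in %s: missing or unparseable `fs` metadata line.", path))
  }
  nf <- count.fields(path, sep = ",", comment.char = "#")
  if (length(unique(nf)) != 1L) {
    abort(sprintf("Format error in %s: ragged rows (field counts %s).",
                  path, paste(unique(nf), collapse = ", ")))
  }
  df <- read.csv(path, comment.char = "#", header = TRUE, check.names = FALSE)
  mat <- t(as.matrix(df))
  storage.mode(mat) <- "double"
  dimnames(mat) <- NULL
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(t(mat)), arr.ind = TRUE)[1, ]
    abort(sprintf("Data error in %s: non-finite value at row %d, column %d (trial %d, sample %d).",
                  path, bad[1], bad[2], bad[2], bad[1]))
  }
  grab <- function(key) if (key %in% names(meta)) meta[[key]] else ""
  trialset(mat, fs = as.numeric(meta[["fs"]]),
           protocol = if (nzchar(grab("protocol"))) grab("protocol") else "NI",
           subject = grab("subject"), group = grab("group"),
           age = grab("age"), sex = grab("sex"))
}

fmt_num <- function(x) format(x, digits = 15, trim = TRUE, scientific = TRUE)

#' Write pipeline result tables to a directory
#'
#' Emits three delimited-text files: `mse_curves.csv` (a `scale` column
#' plus one entropy column per subject; all curves must share a scale
#' axis), `complexity.csv` (subject, group, protocol, sex, complexity
#' index) and, when supplied, `stats.csv` (the pairwise comparison
#' table). Values are written with 15 significant digits so a read-back
#' reproduces them to at least 12.
#'
#' @param curves Long tibble of curves: columns `subject`, `scale`,
#'   `entropy` (as produced by [run_pipeline()]); may be empty.
#' @param table Complexity table (may be empty).
#' @param path Output directory (created if needed).
#' @param stats Optional pairwise stats table.
#' @return `path`, invisibly.
#' @export
write_results <- function(curves, table, path, stats = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  curve_file <- file.path(path, "mse_curves.csv")
  if (nrow(curves) == 0) {
    writeLines("scale", curve_file)
  } else {
    if (length(unique(tapply(curves$scale, curves$subject, paste, collapse = ","))) != 1L) {
      abort("All curves must share the same scale axis.")
    }
    wide <- tidyr::pivot_wider(curves[c("subject", "scale", "entropy")],
                               names_from = "subject", values_from = "entropy")
    wide <- dplyr::arrange(wide, .data$scale)
    wide <- dplyr::mutate(wide, dplyr::across(-"scale", fmt_num))
    write.csv(wide, curve_file, row.names = FALSE, quote = FALSE)
  }
  tab <- as.data.frame(table)
  if ("index" %in% names(tab)) tab$index <- fmt_num(tab$index)
  if (nrow(tab) == 0 && ncol(tab) == 0) {
    tab <- data.frame(subject = character(), group = character(),
                      protocol = character(), index = character())
  }
  write.csv(tab, file.path(path, "complexity.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(stats)) {
    st <- as.data.frame(stats)
    num <- vapply(st, is.numeric, TRUE)
    st[num] <- lapply(st[num], fmt_num)
    write.csv(st, file.path(path, "stats.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back tables written by [write_results()]
#'
#' @param path Directory containing `mse_curves.csv`, `complexity.csv`
#'   and optionally `stats.csv`.
#' @return A list with `curves` (long tibble: subject, scale, entropy),
#'   `complexity` and `stats` (`NULL` when absent).
#' @export
read_results <- function(path) {
  curve_file <- file.path(path, "mse_curves.csv")
  if (!file.exists(curve_file)) abort(sprintf("No mse_curves.csv under %s.", path))
  wide <- as_tibble(read.csv(curve_file, check.names = FALSE))
  curves <- if (ncol(wide) > 1) {
    tidyr::pivot_longer(wide, -"scale", names_to = "subject", values_to = "entropy")
  } else {
    tibble(scale = integer(), subject = character(), entropy = double())
  }
  comp <- as_tibble(read.csv(file.path(path, "complexity.csv"), check.names = FALSE))
  stats_file <- file.path(path, "stats.csv")
  stats <- if (file.exists(stats_file)) as_tibble(read.csv(stats_file, check.names = FALSE)) else NULL
  list(curves = curves, complexity = comp, stats = stats)
}
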