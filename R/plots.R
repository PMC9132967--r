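#' Plot multiscale entropy curves
#'
#' Thin lines per subject, thick lines per group mean — the standard way
#' multiscale entropy results are displayed.
#'
#' @param curves Long curve tibble (columns `scale`, `entropy`, optionally
#'   `subject` and `group`), e.g. the `curves` element of a
#'   [run_pipeline()] result or a single [mse_curve()].
#' @return A ggplot object.
#' @export
plot_mse_curves <- function(curves) {
  if (!is.data.frame(curves)) abort("`curves` must be a data frame.")
  has_group <- "group" %in% names(curves)
  has_subject <- "subject" %in% names(curves)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$scale, y = .data$entropy))
  if (has_subject && has_group) {
    means <- curves |>
      dplyr::group_by(.data$group, .data$scale) |>
      dplyr::summarise(entropy = mean(.data$entropy), .groups = "drop")
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = .data$subject, colour = .data$group),
                         linewidth = 0.25, alpha = 0.5) +
      ggplot2::geom_line(data = means, ggplot2::aes(colour = .data$group),
                         linewidth = 1.1)
  } else if (has_subject) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$subject), linewidth = 0.4)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.8)
  }
  p + ggplot2::labs(x = "Scale", y = "Entropy (nats)", colour = "Group") +
    ggplot2::theme_minimal()
}

#' @method autoplot mse_curve
#' @export
autoplot.mse_curve <- function(object, ...) plot_mse_curves(object)

#' Plot per-group complexity indices
#'
#' Jittered points per subject with dashed quartile lines (first, second,
#' third) per group.
#'
#' @param table Complexity table with `group` and `index` columns.
#' @return A ggplot object.
#' @export
plot_complexity <- function(table) {
  if (!all(c("group", "index") %in% names(table))) {
    abort("`table` needs `group` and `index` columns.")
  }
  qs <- table |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(q1 = quantile(.data$index, 0.25),
                     q2 = median(.data$index),
                     q3 = quantile(.data$index, 0.75), .groups = "drop") |>
    tidyr::pivot_longer(c("q1", "q2", "q3"), names_to = "quartile", values_to = "value")
  ggplot2::ggplot(table, ggplot2::aes(x = .data$group, y = .data$index, colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_errorbar(data = qs,
                           ggplot2::aes(x = .data$group, ymin = .data$value, ymax = .data$value),
                           inherit.aes = FALSE, width = 0.45, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Complexity index (nats)") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

# across-subject percentile band plot shared by the PSD and coherence panels
band_plot <- function(df, value, ylab, f_max = NULL) {
  band <- df |>
    dplyr::group_by(.data$group, .data$freq) |>
    dplyr::summarise(lo = quantile(.data[[value]], 0.025),
                     mid = mean(.data[[value]]),
                     hi = quantile(.data[[value]], 0.975), .groups = "drop")
  if (!is.null(f_max)) band <- band[band$freq <= f_max, ]
  ggplot2::ggplot(band, ggplot2::aes(x = .data$freq, y = .data$mid,
                                     colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Frequency (Hz)", y = ylab, colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot per-group Welch PSDs with 95% percentile bands
#'
#' The frequency axis is limited to the low-pass cutoff band
#' (default 0-30 Hz) since the analysis signal carries no power above it.
#'
#' @param psd PSD tibble with `group`, `freq`, `psd` columns.
#' @param f_max Upper frequency limit (Hz, default 30).
#' @return A ggplot object.
#' @export
plot_psd <- function(psd, f_max = 30) {
  band_plot(psd, "psd", expression(PSD ~ (units^2 / Hz)), f_max) +
    ggplot2::scale_y_log10()
}

#' Plot stimulus-response coherence with 95% percentile bands
#'
#' @param coh Coherence tibble with `group`, `freq`, `coherence` columns.
#' @param f_max Upper frequency limit (Hz, default 30).
#' @return A ggplot object.
#' @export
plot_coherence <- function(coh, f_max = 30) {
  band_plot(coh, "coherence", "Coherence", f_max)
}

#' @method autoplot muerg_analysis
#' @export
autoplot.muerg_analysis <- function(object, type = c("mse", "complexity", "psd", "coherence"), ...) {
  type <- match.arg(type)
  switch(type,
         mse = plot_mse_curves(object$curves),
         complexity = plot_complexity(object$complexity),
         psd = plot_psd(object$psd),
         coherence = {
           if (is.null(object$coherence)) abort("This analysis has no coherence panel.")
           plot_coherence(object$coherence)
         })
}

#' Write a figure report for a pipeline run
#'
#' Saves static images of the multiscale entropy curves, the complexity
#' strip plot, and the spectral panels (PSD, and coherence when present).
#' No statistics are computed beyond the percentile bands.
#'
#' @param result A `muerg_analysis` from [run_pipeline()].
#' @param path Output directory (created if needed).
#' @param format Image format understood by [ggplot2::ggsave()]
#'   (default `"png"`).
#' @param width,height,dpi Passed to [ggplot2::ggsave()].
#' @return Character vector of the files written, invisibly.
#' @export
plot_report <- function(result, path, format = "png",
                        width = 7, height = 4.5, dpi = 150) {
  if (!inherits(result, "muerg_analysis")) abort("`result` must be a muerg_analysis.")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  panels <- list(mse = autoplot(result, "mse"),
                 complexity = autoplot(result, "complexity"),
                 psd = autoplot(result, "psd"))
  if (!is.null(result$coherence)) panels$coherence <- autoplot(result, "coherence")
  files <- character(0)
  for (nm in names(panels)) {
    f <- file.path(path, paste0(nm, ".", format))
    ggplot2::ggsave(f, panels[[nm]], width = width, height = height, dpi = dpi)
    files <- c(files, f)
  }
  invisible(files)
}
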