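#' Per-group descriptive statistics
#'
#' Median and quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) of a value column per group, the descriptive
#' summary reported for complexity indices when no normality assumption is
#' made.
#'
#' @param g Data frame with at least a grouping column and a value column.
#' @param value Name of the value column (default `"index"`).
#' @param ... Grouping column names (defaults to `"group"`, plus
#'   `"protocol"` if present).
#' @return A tibble with one row per group: `n`, `median`, `q1`, `q3`.
#' @examples
#' tbl <- tibble::tibble(group = rep(c("a", "b"), each = 5), index = 1:10)
#' summarize_groups(tbl)
#' @export
summarize_groups <- function(g, value = "index", ...) {
  if (!is.data.frame(g)) abort("`g` must be a data frame.")
  if (!value %in% names(g)) abort(sprintf("No `%s` column in the table.", value))
  by <- c(...)
  if (length(by) == 0) by <- intersect(c("group", "protocol"), names(g))
  if (length(by) == 0) abort("No grouping columns found; pass them explicitly.")
  out <- g |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data[[value]]),
      q1 = unname(quantile(.data[[value]], 0.25)),
      q3 = unname(quantile(.data[[value]], 0.75)),
      .groups = "drop"
    )
  if (any(out$n < 1)) abort("Empty group encountered.")
  out
}

#' Mann-Whitney U test between two samples
#'
#' Two-sided rank test of stochastic equality. The exact null distribution
#' is used when both samples have at most `exact_max_n` observations and
#' there are no ties; otherwise the normal approximation with continuity
#' and tie correction is used. When every value in both samples is
#' identical the test is degenerate: a warning is raised and `p = 1`,
#' `U = n_a * n_b / 2` returned.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @param exact_max_n Largest per-group size for the exact test
#'   (default 12).
#' @return A one-row tibble: `n_a`, `n_b`, `U` (number of (a, b) pairs
#'   with a > b, ties counted 1/2), `p` (two-sided), `median_a`,
#'   `median_b`, `q1_a`, `q3_a`, `q1_b`, `q3_b`, `method`, `alpha`,
#'   `significant`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, alpha = 0.05, exact_max_n = 12) {
  a <- as.double(a)
  b <- as.double(b)
  if (length(a) < 1 || length(b) < 1) abort("Both samples must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0
  degenerate <- length(unique(c(a, b))) == 1L
  if (degenerate) {
    warn("All values identical in both groups; the rank test is degenerate (p = 1).")
    U <- length(a) * length(b) / 2
    p <- 1
    method <- "degenerate"
  } else {
    exact <- !ties && length(a) <= exact_max_n && length(b) <= exact_max_n
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = TRUE)
    )
    U <- unname(wt$statistic)
    p <- min(wt$p.value, 1)
    method <- if (exact) "exact" else "normal_approx"
  }
  tibble(
    n_a = length(a), n_b = length(b), U = U, p = p,
    median_a = median(a), median_b = median(b),
    q1_a = unname(quantile(a, 0.25)), q3_a = unname(quantile(a, 0.75)),
    q1_b = unname(quantile(b, 0.25)), q3_b = unname(quantile(b, 0.75)),
    method = method, alpha = alpha, significant = p < alpha
  )
}

# significance stars at the conventional 0.05 / 0.01 cutpoints
p_stars <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

#' All pairwise group comparisons of a complexity table
#'
#' Runs [mann_whitney()] on every unordered pair of groups, separately per
#' protocol when a `protocol` column is present (four groups give six
#' pairs per protocol). P-values are reported unadjusted — matching the
#' analysis convention the package reproduces — with a Holm-adjusted
#' column (`p_holm`, computed within protocol) alongside for users who
#' want family-wise control.
#'
#' @param g Group table: one row per subject with `group`, a value column
#'   and optionally `protocol`.
#' @param value Name of the value column (default `"index"`).
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per comparison: `protocol` (if any),
#'   `group_a`, `group_b`, the [mann_whitney()] columns, `p_holm` and
#'   `stars`.
#' @export
compare_all_pairs <- function(g, value = "index", alpha = 0.05) {
  if (!is.data.frame(g) || !"group" %in% names(g)) abort("`g` needs a `group` column.")
  if (!value %in% names(g)) abort(sprintf("No `%s` column in the table.", value))
  has_proto <- "protocol" %in% names(g)
  protos <- if (has_proto) unique(g$protocol) else NA_character_
  res <- purrr::map(protos, function(proto) {
    sub <- if (has_proto) g[g$protocol == proto, ] else g
    groups <- unique(sub$group)
    if (length(groups) < 2) abort("Need at least two groups to compare.")
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    tab <- purrr::map(pairs, function(pr) {
      r <- mann_whitney(sub[[value]][sub$group == pr[1]],
                        sub[[value]][sub$group == pr[2]], alpha = alpha)
      dplyr::bind_cols(tibble(group_a = pr[1], group_b = pr[2]), r)
    }) |> dplyr::bind_rows()
    tab$p_holm <- p.adjust(tab$p, method = "holm")
    if (has_proto) tab <- dplyr::bind_cols(tibble(protocol = proto), tab)
    tab
  }) |> dplyr::bind_rows()
  res$stars <- p_stars(res$p)
  res
}
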