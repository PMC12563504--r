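sig_label <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "NA",
    p < 0.05 ~ "significant",
    p <= 0.10 ~ "trend",
    TRUE ~ "ns"
  )
}

#' Kruskal-Wallis rank-sum test (tidy wrapper)
#'
#' Tie-corrected Kruskal-Wallis H on mid-ranks with the chi-square
#' approximation on `k - 1` degrees of freedom, via [stats::kruskal.test()].
#' A fully degenerate input (every value identical across all groups) is
#' reported as `H = 0`, `p = 1` with `degenerate = TRUE` instead of NaN.
#'
#' @param data A data frame.
#' @param value,group Bare column names of the response and the grouping
#'   variable (at least two non-empty groups, total n >= 3).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `n`,
#'   `n_per_group` (string `"n1/n2/..."`), `degenerate`.
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 2), y = 1:6)
#' kw_test(d, y, g)
kw_test <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  ns <- table(g)
  if (nlevels(g) < 2L) abort("kw_test needs at least two groups")
  if (length(y) < 3L) abort("kw_test needs total n >= 3")
  if (length(unique(y)) == 1L) {
    return(tibble(method = "Kruskal-Wallis", statistic = 0,
                  df = nlevels(g) - 1, p_value = 1, n = length(y),
                  n_per_group = paste(ns, collapse = "/"),
                  degenerate = TRUE))
  }
  kt <- stats::kruskal.test(y, g)
  tibble(method = "Kruskal-Wallis", statistic = unname(kt$statistic),
         df = unname(kt$parameter), p_value = kt$p.value, n = length(y),
         n_per_group = paste(ns, collapse = "/"), degenerate = FALSE)
}

#' Mann-Whitney U test (tidy wrapper)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test via
#' [stats::wilcox.test()], reporting the U statistic for the first group.
#' The exact null distribution is enumerated when both groups have n <= 20
#' and the data are tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param data A data frame.
#' @param value,group Bare column names; `group` must have exactly two
#'   levels (first level by factor order is "x").
#' @return One-row tibble: `method`, `statistic` (U), `p_value`, `n`,
#'   `n_per_group`, `exact` (whether the exact distribution was used).
#' @export
#' @examples
#' d <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' mw_test(d, y, g)
mw_test <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2L) abort("mw_test needs exactly two groups")
  x1 <- y[g == levels(g)[1]]
  x2 <- y[g == levels(g)[2]]
  if (!length(x1) || !length(x2)) abort("both groups must be non-empty")
  ties <- anyDuplicated(y) > 0
  exact <- length(x1) <= 20 && length(x2) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x1, x2, exact = exact, correct = TRUE))
  tibble(method = "Mann-Whitney U", statistic = unname(wt$statistic),
         p_value = wt$p.value, n = length(y),
         n_per_group = paste(c(length(x1), length(x2)), collapse = "/"),
         exact = exact)
}

#' Chi-square test of independence (tidy wrapper)
#'
#' Pearson chi-square on an r x c contingency table with
#' `(r - 1)(c - 1)` degrees of freedom; the Yates continuity correction is
#' applied when requested and the table is 2 x 2. Tables with a zero margin
#' are rejected.
#'
#' @param table An r x c matrix (or table) of counts, r, c >= 2.
#' @param yates Apply the continuity correction for 2 x 2 tables
#'   (default `TRUE`).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' chi_sq_independence(matrix(c(118, 57, 140, 77), 2, byrow = TRUE))
chi_sq_independence <- function(table, yates = TRUE) {
  m <- as.matrix(table)
  if (any(m < 0) || anyNA(m)) abort("counts must be non-negative")
  if (nrow(m) < 2L || ncol(m) < 2L) abort("table must be at least 2 x 2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero row or column margin; test undefined")
  }
  correct <- yates && nrow(m) == 2L && ncol(m) == 2L
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble(method = if (correct) "Chi-square (Yates)" else "Chi-square",
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, n = sum(m))
}

#' Shapiro-Wilk normality screen
#'
#' Shapiro-Wilk test via [stats::shapiro.test()] with a `verdict` column:
#' `"non-normal"` when p < 0.05, `"normal"` otherwise. Requires
#' 3 <= n <= 5000 and a non-constant sample.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `method`, `statistic` (W), `p_value`, `n`,
#'   `verdict`.
#' @export
#' @examples
#' normality_screen(rnorm(100))
normality_screen <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    abort("normality_screen requires 3 <= n <= 5000")
  }
  if (length(unique(x)) == 1L) abort("constant sample; test undefined")
  st <- stats::shapiro.test(x)
  tibble(method = "Shapiro-Wilk", statistic = unname(st$statistic),
         p_value = st$p.value, n = length(x),
         verdict = if (st$p.value < 0.05) "non-normal" else "normal")
}

#' Per-feature Kruskal-Wallis screen across groups
#'
#' Runs [kw_test()] for every feature column of a feature matrix against one
#' grouping variable, with optional Benjamini-Hochberg adjustment, and labels
#' each raw p-value (`significant` p < 0.05, `trend` 0.05-0.10, `ns`).
#'
#' @param features Feature tibble (e.g. from [simulate_features()]) holding
#'   the grouping column and the feature columns.
#' @param group Bare column name of the grouping variable.
#' @param feature_cols Character vector of feature columns
#'   (default [feature_names()]).
#' @param bh Add a `p_bh` Benjamini-Hochberg column (default `FALSE`; the
#'   primary report is raw per-feature p-values).
#' @return Tibble with one row per feature: `feature`, `statistic`, `df`,
#'   `p_value`, `label` (and `p_bh` when requested).
#' @export
kw_features <- function(features, group, feature_cols = feature_names(),
                        bh = FALSE) {
  missing_cols <- setdiff(feature_cols, names(features))
  if (length(missing_cols)) {
    abort(paste0("missing feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  res <- purrr::map_dfr(feature_cols, function(fc) {
    kt <- kw_test(features, !!rlang::sym(fc), {{ group }})
    tibble(feature = fc, statistic = kt$statistic, df = kt$df,
           p_value = kt$p_value)
  })
  res$label <- sig_label(res$p_value)
  if (bh) res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res
}
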