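# Cell-mean machinery shared by alignment, diagnostics and post hoc.
# Margins are unweighted means of cell means (Type-III convention), so the
# construction is exact for unbalanced but complete layouts.
art_cell_decomposition <- function(y, fa, fb) {
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(paste0("empty design cell: ", rownames(cells)[empty[1]], " x ",
                 colnames(cells)[empty[2]]))
  }
  m_ab <- tapply(y, list(fa, fb), mean)
  ma <- rowMeans(m_ab)
  mb <- colMeans(m_ab)
  mu <- mean(m_ab)
  ia <- as.integer(fa)
  ib <- as.integer(fb)
  cell_mean <- m_ab[cbind(ia, ib)]
  resid <- y - cell_mean
  list(
    resid = resid,
    eff_a = ma[ia] - mu,
    eff_b = mb[ib] - mu,
    eff_ab = cell_mean - ma[ia] - mb[ib] + mu
  )
}

# max |off-target effect estimate| left in an aligned response
offtarget_residual <- function(aligned, fa, fb, target) {
  d <- art_cell_decomposition(aligned, fa, fb)
  keep <- setdiff(c("eff_a", "eff_b", "eff_ab"), target)
  max(vapply(d[keep], function(e) max(abs(e)), numeric(1)))
}

prep_factors <- function(data, y_quo, a_quo, b_quo) {
  y <- dplyr::pull(data, !!y_quo)
  fa <- droplevels(as.factor(dplyr::pull(data, !!a_quo)))
  fb <- droplevels(as.factor(dplyr::pull(data, !!b_quo)))
  if (anyNA(y) || any(!is.finite(y))) abort("response must be finite")
  if (anyNA(fa) || anyNA(fb)) abort("factor labels must be non-missing")
  if (nlevels(fa) < 2L || nlevels(fb) < 2L) {
    abort("both factors need at least two levels")
  }
  list(y = y, fa = fa, fb = fb,
       a_name = as_name(a_quo), b_name = as_name(b_quo))
}

#' Aligned responses for a two-factor design (ART construction)
#'
#' For each effect of a two-way between-subjects layout (factor A, factor B,
#' their interaction), strips the estimated contributions of the *other*
#' effects from the response: the aligned response for an effect is the
#' within-cell residual plus that effect's own estimated contribution, where
#' effect estimates come from cell means with unweighted margins. Ranking
#' these aligned responses and running a factorial ANOVA on the ranks — keeping
#' only the target effect from each fit — is the aligned rank transform (ART)
#' procedure.
#'
#' @param data A data frame with one row per subject.
#' @param y,A,B Bare column names: numeric response and the two
#'   between-subjects factors. Every A x B cell must be non-empty.
#' @return The input data plus three columns `aligned_A`, `aligned_B`,
#'   `aligned_interaction` (named after the actual factor columns), and an
#'   attribute `"diagnostics"`: per effect, the largest off-target effect
#'   estimate left in its aligned response (0 up to floating error by
#'   construction).
#' @export
#' @examples
#' d <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:3)
#' d$y <- rnorm(nrow(d))
#' art_align(d, y, a, b)
art_align <- function(data, y, A, B) {
  pf <- prep_factors(data, enquo(y), enquo(A), enquo(B))
  d <- art_cell_decomposition(pf$y, pf$fa, pf$fb)
  out <- as_tibble(data)
  nm_a <- paste0("aligned_", pf$a_name)
  nm_b <- paste0("aligned_", pf$b_name)
  out[[nm_a]] <- d$resid + d$eff_a
  out[[nm_b]] <- d$resid + d$eff_b
  out[["aligned_interaction"]] <- d$resid + d$eff_ab
  attr(out, "diagnostics") <- tibble(
    effect = c(pf$a_name, pf$b_name, "interaction"),
    max_offtarget = c(
      offtarget_residual(out[[nm_a]], pf$fa, pf$fb, "eff_a"),
      offtarget_residual(out[[nm_b]], pf$fa, pf$fb, "eff_b"),
      offtarget_residual(out[["aligned_interaction"]], pf$fa, pf$fb, "eff_ab")
    ))
  out
}

rank_anova_effect <- function(aligned, fa, fb, which_row) {
  r <- rank(aligned)
  fit <- lm(r ~ fa * fb,
            contrasts = list(fa = "contr.sum", fb = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  row <- an[which_row, ]
  c(statistic = row[["F value"]], df1 = row[["Df"]],
    df2 = an["Residuals", "Df"], p_value = row[["Pr(>F)"]])
}

#' Two-way aligned rank transform (ART) ANOVA
#'
#' Nonparametric factorial analysis for a two-factor between-subjects
#' design: for each effect (A, B, A x B) the response is aligned for that
#' effect ([art_align()]), mid-ranked, and a full two-factor fixed-effects
#' ANOVA is fitted on the ranks (Type-III sums of squares with sum-to-zero
#' contrasts, so unbalanced cells are handled); only the target effect's F
#' and p are kept from each fit.
#'
#' @inheritParams art_align
#' @return An object of class `"art_anova"`: a list with `effects` (tibble:
#'   `effect`, `statistic` (F), `df1`, `df2`, `p_value`, `label`),
#'   `diagnostics` (per-effect alignment residuals), `n`, `cell_counts`, and
#'   the factor names. [tidy()] returns the effects tibble, [glance()] a
#'   one-row model summary.
#' @export
#' @examples
#' d <- tidyr::expand_grid(a = c("x", "y", "z"), b = c("u", "v"), rep = 1:5)
#' d$y <- rnorm(nrow(d))
#' art_anova(d, y, a, b)
art_anova <- function(data, y, A, B) {
  pf <- prep_factors(data, enquo(y), enquo(A), enquo(B))
  aligned <- art_align(data, {{ y }}, {{ A }}, {{ B }})
  nm_a <- paste0("aligned_", pf$a_name)
  nm_b <- paste0("aligned_", pf$b_name)
  rows <- rbind(
    rank_anova_effect(aligned[[nm_a]], pf$fa, pf$fb, "fa"),
    rank_anova_effect(aligned[[nm_b]], pf$fa, pf$fb, "fb"),
    rank_anova_effect(aligned[["aligned_interaction"]], pf$fa, pf$fb,
                      "fa:fb"))
  effects <- as_tibble(rows)
  effects <- dplyr::bind_cols(
    tibble(effect = c(pf$a_name, pf$b_name, "interaction")), effects)
  effects$label <- sig_label(effects$p_value)
  out <- list(effects = effects,
              diagnostics = attr(aligned, "diagnostics"),
              n = length(pf$y),
              cell_counts = table(pf$fa, pf$fb),
              factors = c(A = pf$a_name, B = pf$b_name))
  class(out) <- "art_anova"
  out
}

#' @export
print.art_anova <- function(x, ...) {
  cat("Two-way ART ANOVA (", x$factors[["A"]], " x ", x$factors[["B"]],
      "), n = ", x$n, "\n", sep = "")
  df <- as.data.frame(x$effects)
  df$statistic <- round(df$statistic, 2)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ART ANOVA fit
#'
#' @param x An `"art_anova"` object.
#' @param ... Unused.
#' @return The per-effect tibble: `effect`, `statistic`, `df1`, `df2`,
#'   `p_value`, `label`.
#' @export
tidy.art_anova <- function(x, ...) x$effects

#' One-row summary of an ART ANOVA fit
#'
#' @param x An `"art_anova"` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_cells`, `df2` and the largest alignment
#'   residual (should be ~0).
#' @export
glance.art_anova <- function(x, ...) {
  tibble(n = x$n, n_cells = length(x$cell_counts),
         df2 = x$effects$df2[1],
         max_alignment_residual = max(x$diagnostics$max_offtarget))
}

#' Post hoc pairwise contrasts for an ART main effect
#'
#' Tukey-adjusted pairwise contrasts between the levels of one main effect,
#' computed on the factor-aligned mid-ranks: the response is aligned for the
#' chosen factor, ranked, refitted (`lm` on ranks, sum contrasts), and
#' `emmeans` pairwise contrasts with Tukey adjustment are extracted. The
#' reported `direction` gives the sign of each contrast on the aligned-rank
#' scale.
#'
#' @inheritParams art_align
#' @param factor Bare column name of the main effect to decompose (one of
#'   `A` or `B`).
#' @return Tibble: `contrast`, `estimate`, `se`, `df`, `statistic`,
#'   `p_value` (Tukey-adjusted), `direction` (e.g. `"BD < SCH"`), `label`.
#' @export
#' @examples
#' d <- tidyr::expand_grid(a = c("x", "y", "z"), b = c("u", "v"), rep = 1:5)
#' d$y <- rnorm(nrow(d)) + as.integer(factor(d$a))
#' art_posthoc(d, y, a, b, factor = a)
art_posthoc <- function(data, y, A, B, factor) {
  pf <- prep_factors(data, enquo(y), enquo(A), enquo(B))
  f_name <- as_name(enquo(factor))
  if (!f_name %in% c(pf$a_name, pf$b_name)) {
    abort("factor must be one of the two design factors")
  }
  aligned <- art_align(data, {{ y }}, {{ A }}, {{ B }})
  r <- rank(aligned[[paste0("aligned_", f_name)]])
  dd <- data.frame(r = r, fa = pf$fa, fb = pf$fb)
  fit <- lm(r ~ fa * fb, data = dd,
            contrasts = list(fa = "contr.sum", fb = "contr.sum"))
  target <- if (f_name == pf$a_name) "fa" else "fb"
  # the factor's aligned response intentionally carries only its own effect,
  # so emmeans' interaction caveat does not apply
  emm <- suppressMessages(emmeans::emmeans(fit, specs = target))
  cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  levs <- strsplit(as.character(cmp$contrast), " - ", fixed = TRUE)
  direction <- vapply(seq_len(nrow(cmp)), function(i) {
    l <- levs[[i]]
    if (cmp$estimate[i] < 0) paste(l[1], "<", l[2]) else
      paste(l[1], ">", l[2])
  }, character(1))
  tibble(contrast = as.character(cmp$contrast), estimate = cmp$estimate,
         se = cmp$SE, df = cmp$df, statistic = cmp$t.ratio,
         p_value = cmp$p.value, direction = direction,
         label = sig_label(cmp$p.value))
}
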