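#' Demographic summary and between-group demographic tests
#'
#' Builds the cohort's demographic table (counts and percentages by
#' diagnosis x suicide-attempt cell, sex and - when present - age), and runs
#' the demographic comparisons: chi-square of independence for sex between
#' SA and non-SA patients (Yates-corrected 2 x 2) and across the three
#' groups (SA / non-SA / unaffected), and, when an `age` column is present,
#' a Mann-Whitney test of age between SA and non-SA patients and a
#' Kruskal-Wallis test across the three groups.
#'
#' @param genotypes A validated genotype tibble (optionally with `age`).
#' @return A list: `counts` (per-cell tibble with `n`, `n_female`,
#'   `pct_female`, `pct_of_patients`), `shares` (one-row tibble with the
#'   headline percentages: `sa_pct`, `nonsa_pct`, `bd_pct`, `mdd_pct`,
#'   `sch_pct` of patients), and `tests` (tibble of test results; empty
#'   with a notice when fewer than two groups are present).
#' @export
#' @examples
#' g <- generate_genotypes(default_study_design(), seed = 1)
#' summarize_demographics(g)$shares
summarize_demographics <- function(genotypes) {
  g <- as_tibble(genotypes)
  if (nrow(g) == 0L) abort("no records")
  counts <- g |>
    dplyr::count(.data$diagnosis, .data$sa_status, name = "n") |>
    dplyr::left_join(
      g |> dplyr::filter(.data$sex == "female") |>
        dplyr::count(.data$diagnosis, .data$sa_status, name = "n_female"),
      by = c("diagnosis", "sa_status")) |>
    dplyr::mutate(n_female = dplyr::coalesce(.data$n_female, 0L),
                  pct_female = 100 * .data$n_female / .data$n)
  patients <- g[g$diagnosis != "UNAFFECTED", ]
  n_pat <- nrow(patients)
  counts$pct_of_patients <- ifelse(
    counts$diagnosis == "UNAFFECTED", NA_real_,
    100 * counts$n / max(n_pat, 1L))
  shares <- tibble(
    n_patients = n_pat,
    n_unaffected = sum(g$diagnosis == "UNAFFECTED"),
    sa_pct = 100 * sum(patients$sa_status == "SA") / max(n_pat, 1L),
    nonsa_pct = 100 * sum(patients$sa_status == "NONSA") / max(n_pat, 1L),
    bd_pct = 100 * sum(patients$diagnosis == "BD") / max(n_pat, 1L),
    mdd_pct = 100 * sum(patients$diagnosis == "MDD") / max(n_pat, 1L),
    sch_pct = 100 * sum(patients$diagnosis == "SCH") / max(n_pat, 1L)
  )
  tests <- list()
  if (n_pat > 0 && length(unique(patients$sa_status)) == 2L) {
    tab2 <- table(patients$sex, patients$sa_status)
    tests$sex_sa <- chi_sq_independence(tab2, yates = TRUE) |>
      dplyr::mutate(comparison = "sex: SA vs non-SA patients")
    if ("age" %in% names(patients) && sum(!is.na(patients$age)) > 3) {
      tests$age_sa <- mw_test(patients, age, sa_status) |>
        dplyr::mutate(comparison = "age: SA vs non-SA patients")
    }
  }
  g$group3 <- ifelse(g$diagnosis == "UNAFFECTED", "UNAFFECTED", g$sa_status)
  if (length(unique(g$group3)) >= 2L) {
    tab3 <- table(g$sex, g$group3)
    if (all(dim(tab3) >= 2) && all(rowSums(tab3) > 0) &&
        all(colSums(tab3) > 0)) {
      tests$sex_3 <- chi_sq_independence(tab3, yates = TRUE) |>
        dplyr::mutate(comparison = "sex: SA / non-SA / unaffected")
    }
    if ("age" %in% names(g) && sum(!is.na(g$age)) > 3 &&
        length(unique(g$group3)) >= 3L) {
      tests$age_3 <- kw_test(g, age, group3) |>
        dplyr::mutate(comparison = "age: SA / non-SA / unaffected")
    }
  }
  tests_tbl <- if (length(tests)) dplyr::bind_rows(tests) else {
    message("fewer than two groups; demographic tests skipped")
    tibble()
  }
  list(counts = counts, shares = shares, tests = tests_tbl)
}

#' Run the full genotype-to-statistics analysis
#'
#' End-to-end orchestration: genotypes -> activity coefficients ->
#' per-individual ODE simulation -> 30-feature matrix -> group statistics.
#' The statistical battery mirrors the study layout: (a) demographic summary
#' and tests ([summarize_demographics()]); (b) per-feature Kruskal-Wallis
#' comparison across the three groups SA patients / non-SA patients /
#' unaffected; (c) per-feature two-way ART ANOVA in patients with diagnosis
#' and suicide-attempt status as fixed between-subjects factors; (d)
#' Tukey-adjusted post hoc diagnosis contrasts for features with a
#' significant diagnosis main effect. With fewer than two individuals per
#' required group the statistics stages are skipped with a notice.
#'
#' @param genotypes Genotype tibble (e.g. from [generate_genotypes()] or
#'   [read_genotypes()]).
#' @param specs Variant-spec table ([default_variant_specs()]).
#' @param params Kinetic parameters ([kinetic_defaults()]).
#' @param feature_cache Optional feature lookup ([build_feature_cache()]).
#' @param posthoc Run post hoc contrasts for significant diagnosis effects
#'   (default `TRUE`).
#' @param bh Add Benjamini-Hochberg columns to the per-feature tables
#'   (default `FALSE`; raw per-feature p-values are the primary report).
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `kruskal_wallis.csv`, `art_anova.csv`, `posthoc.csv`,
#'   `demographics.csv` and `resolved_config.json` into it.
#' @return A list of class `"presynapse_analysis"`: `demographics`,
#'   `features`, `kruskal_wallis`, `art`, `posthoc`, `config`.
#' @export
#' @examples
#' \donttest{
#' g <- generate_genotypes(default_study_design(), seed = 1)
#' res <- run_presynapse_analysis(g, params = kinetic_defaults(t_end = 120))
#' head(res$kruskal_wallis)
#' }
run_presynapse_analysis <- function(genotypes,
                                    specs = default_variant_specs(),
                                    params = kinetic_defaults(),
                                    feature_cache = NULL,
                                    posthoc = TRUE, bh = FALSE,
                                    out_dir = NULL) {
  validate_genotypes(genotypes, specs)
  activity <- compute_activity(genotypes, specs)
  features <- simulate_features(activity, params, feature_cache)
  features$group3 <- ifelse(features$diagnosis == "UNAFFECTED",
                            "UNAFFECTED", features$sa_status)
  kw_tbl <- NULL
  if (length(unique(features$group3)) >= 2L &&
      nrow(features) >= 3L) {
    kw_tbl <- kw_features(features, group3, bh = bh)
  } else {
    message("fewer than two comparison groups; Kruskal-Wallis stage skipped")
  }
  patients <- features[features$diagnosis != "UNAFFECTED", ]
  art_tbl <- NULL
  posthoc_tbl <- NULL
  cells_ok <- nrow(patients) > 0 &&
    length(unique(patients$diagnosis)) >= 2L &&
    length(unique(patients$sa_status)) == 2L &&
    all(table(patients$diagnosis, patients$sa_status) > 0)
  if (cells_ok) {
    art_list <- purrr::map(feature_names(), function(fc) {
      fit <- art_anova(patients, !!rlang::sym(fc), diagnosis, sa_status)
      dplyr::bind_cols(tibble(feature = fc), tidy(fit))
    })
    art_tbl <- dplyr::bind_rows(art_list)
    if (bh) {
      art_tbl <- art_tbl |>
        dplyr::group_by(.data$effect) |>
        dplyr::mutate(p_bh = stats::p.adjust(.data$p_value, "BH")) |>
        dplyr::ungroup()
    }
    if (posthoc) {
      sig <- art_tbl$feature[art_tbl$effect == "diagnosis" &
                               art_tbl$p_value < 0.05]
      if (length(sig)) {
        posthoc_tbl <- purrr::map_dfr(sig, function(fc) {
          dplyr::bind_cols(
            tibble(feature = fc),
            art_posthoc(patients, !!rlang::sym(fc), diagnosis,
                        sa_status, factor = diagnosis))
        })
      }
    }
  } else {
    message("incomplete diagnosis x SA layout; ART ANOVA stage skipped")
  }
  config <- list(
    n = nrow(genotypes),
    variant_specs = as.data.frame(specs),
    kinetics = unclass(params),
    posthoc = posthoc, bh = bh
  )
  out <- list(demographics = summarize_demographics(genotypes),
              features = features, kruskal_wallis = kw_tbl,
              art = art_tbl, posthoc = posthoc_tbl, config = config)
  class(out) <- "presynapse_analysis"
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' Write analysis artifacts to a directory
#'
#' @param analysis A `"presynapse_analysis"` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, nm) {
    if (!is.null(x)) {
      readr::write_csv(x, file.path(out_dir, nm), progress = FALSE)
    }
  }
  w(analysis$features, "features.csv")
  w(analysis$kruskal_wallis, "kruskal_wallis.csv")
  w(analysis$art, "art_anova.csv")
  w(analysis$posthoc, "posthoc.csv")
  w(analysis$demographics$counts, "demographics.csv")
  w(analysis$demographics$tests, "demographic_tests.csv")
  jsonlite::write_json(analysis$config,
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.presynapse_analysis <- function(x, ...) {
  cat("Presynaptic 5-HT analysis: n =", x$config$n, "individuals\n")
  sh <- x$demographics$shares
  cat(sprintf("  patients %d (SA %.2f%%), unaffected %d\n",
              sh$n_patients, sh$sa_pct, sh$n_unaffected))
  if (!is.null(x$kruskal_wallis)) {
    cat("  Kruskal-Wallis (3 groups):",
        sum(x$kruskal_wallis$p_value < 0.05), "of",
        nrow(x$kruskal_wallis), "features significant\n")
  }
  if (!is.null(x$art)) {
    for (eff in unique(x$art$effect)) {
      sub <- x$art[x$art$effect == eff, ]
      cat(sprintf("  ART %s: %d of %d features significant\n", eff,
                  sum(sub$p_value < 0.05), nrow(sub)))
    }
  }
  invisible(x)
}
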