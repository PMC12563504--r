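# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default allele frequencies for the synthetic cohort
#'
#' Shared (group-neutral) allele frequencies used when a design does not
#' override them. These are configurable placeholders chosen in the common
#' population range for each polymorphism, not estimates from any specific
#' cohort; no package result depends on their exact values.
#'
#' @return Named list `variant_id -> named frequency vector` (each summing
#'   to 1).
#' @export
default_allele_freqs <- function() {
  list(
    rs111798998 = c(A = 0.65, G = 0.35),
    rs4290270   = c(T = 0.60, A = 0.40),
    rs7305115   = c(G = 0.55, A = 0.45),
    HTTLPR      = c(S = 0.45, L = 0.55),
    uVNTR       = c("2R" = 0.015, "3R" = 0.60, "3.5R" = 0.02,
                    "4R" = 0.35, "5R" = 0.015)
  )
}

#' Construct a synthetic-cohort design
#'
#' A cohort design bundles the group layout (diagnosis x suicide-attempt
#' cell sizes with exact female counts), the allele frequencies (shared, plus
#' optional per-diagnosis overrides used by [inject_effect()]), and an
#' optional per-cell age model.
#'
#' @param cells Tibble with columns `diagnosis`, `sa_status` (`NA` for
#'   `UNAFFECTED`), `n`, `n_female` (and optionally `age_mean`, `age_sd`).
#' @param allele_freqs Named list as [default_allele_freqs()].
#' @param group_freqs Optional named list `diagnosis -> variant_id -> named
#'   frequency vector` overriding `allele_freqs` within that diagnosis.
#' @return A list of class `"cohort_design"`.
#' @export
cohort_design <- function(cells, allele_freqs = default_allele_freqs(),
                          group_freqs = NULL) {
  cells <- as_tibble(cells)
  need <- c("diagnosis", "sa_status", "n", "n_female")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    abort(paste0("cells lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(cells$n < 0) || any(cells$n_female < 0) ||
      any(cells$n_female > cells$n)) {
    abort("cell sizes must satisfy 0 <= n_female <= n")
  }
  check_freqs <- function(fr, where) {
    for (vid in names(fr)) {
      f <- fr[[vid]]
      if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
        abort(paste0("allele frequencies for ", vid, " in ", where,
                     " must be >= 0 and sum to 1"))
      }
    }
  }
  check_freqs(allele_freqs, "allele_freqs")
  missing_v <- setdiff(VARIANT_IDS, names(allele_freqs))
  if (length(missing_v)) {
    abort(paste0("allele_freqs lacks variant(s): ",
                 paste(missing_v, collapse = ", ")))
  }
  if (!is.null(group_freqs)) {
    for (g in names(group_freqs)) check_freqs(group_freqs[[g]],
                                              paste0("group ", g))
  }
  structure(list(cells = cells, allele_freqs = allele_freqs,
                 group_freqs = group_freqs %||% list()),
            class = "cohort_design")
}

#' The study's cohort layout
#'
#' The diagnosis x suicide-attempt-status layout of the modelled cohort:
#' 392 patients (BD 101 = 46 SA / 55 non-SA; MDD 148 = 76 / 72; SCH 143 =
#' 53 / 90; SA 175 and non-SA 217 overall) plus 140 unaffected individuals,
#' with the exact female count and the age mean/SD of each cell. Allele
#' frequencies are the neutral defaults ([default_allele_freqs()]), shared
#' by every group.
#'
#' @return A `"cohort_design"`.
#' @export
#' @examples
#' d <- default_study_design()
#' sum(d$cells$n)
default_study_design <- function() {
  cells <- tibble(
    diagnosis = c("BD", "BD", "MDD", "MDD", "SCH", "SCH", "UNAFFECTED"),
    sa_status = c("SA", "NONSA", "SA", "NONSA", "SA", "NONSA", NA),
    n         = c(46, 55, 76, 72, 53, 90, 140),
    n_female  = c(34, 43, 55, 44, 29, 53, 48),
    age_mean  = c(43.74, 39.05, 47.91, 50.99, 31.11, 35.47, 40.34),
    age_sd    = c(11.7, 10.9, 9.7, 8.2, 8.7, 9.5, 11.19)
  )
  cohort_design(cells)
}

#' Shift one allele's frequency in one diagnosis group
#'
#' Returns a new design in which `allele`'s frequency at `variant_id` is
#' increased by `delta` within `diagnosis`, with the remaining alleles
#' rescaled proportionally (so the map still sums to 1). Applying the
#' inverse shift restores the original frequencies. Used to create
#' detectable group effects for power and recovery studies.
#'
#' @param design A `"cohort_design"`.
#' @param diagnosis Diagnosis group to shift (e.g. `"SCH"`).
#' @param variant_id Variant to shift (e.g. `"uVNTR"`).
#' @param allele Allele whose frequency moves (e.g. `"4R"`).
#' @param delta Frequency change; the result must stay in [0, 1].
#' @return A new `"cohort_design"`; the input is unchanged.
#' @export
#' @examples
#' d <- inject_effect(default_study_design(), "SCH", "uVNTR", "4R", 0.3)
#' d$group_freqs$SCH$uVNTR
inject_effect <- function(design, diagnosis, variant_id, allele, delta) {
  stopifnot(inherits(design, "cohort_design"))
  if (!diagnosis %in% design$cells$diagnosis) {
    abort(paste0("unknown diagnosis group: ", diagnosis))
  }
  base <- design$group_freqs[[diagnosis]][[variant_id]] %||%
    design$allele_freqs[[variant_id]]
  if (is.null(base)) abort(paste0("unknown variant: ", variant_id))
  if (!allele %in% names(base)) {
    abort(paste0("unknown allele '", allele, "' at ", variant_id))
  }
  p <- base[[allele]]
  p_new <- p + delta
  if (p_new < -1e-12 || p_new > 1 + 1e-12) {
    abort("shifted frequency outside [0, 1]")
  }
  p_new <- min(max(p_new, 0), 1)
  out <- base
  others <- setdiff(names(base), allele)
  if (sum(base[others]) > 0) {
    out[others] <- base[others] * (1 - p_new) / (1 - p)
  } else if (p_new < 1) {
    abort("cannot rescale: all remaining alleles have frequency 0")
  }
  out[[allele]] <- p_new
  gf <- design$group_freqs
  gf[[diagnosis]] <- gf[[diagnosis]] %||% list()
  gf[[diagnosis]][[variant_id]] <- out
  structure(list(cells = design$cells, allele_freqs = design$allele_freqs,
                 group_freqs = gf),
            class = "cohort_design")
}

draw_diploid <- function(n, freqs) {
  a1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  a2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
  # canonical allele order within a call so round-trips are stable
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' Generate a synthetic genotype cohort
#'
#' Draws a genotype table under a cohort design: within each diagnosis x
#' suicide-attempt cell, autosomal genotypes follow Hardy-Weinberg
#' proportions at the design's allele frequencies (two independent allele
#' draws), and the X-linked MAOA uVNTR is drawn per X chromosome - two
#' alleles for females, one for males. Sex counts match the design exactly.
#' Each cell uses its own deterministic substream derived from `seed`, so
#' changing one group's size leaves the other groups' draws unchanged.
#'
#' @param design A `"cohort_design"`.
#' @param seed Integer master seed.
#' @param ages If `TRUE` and the design's cells carry `age_mean`/`age_sd`,
#'   add a normally distributed `age` column (default `FALSE`; no modelled
#'   quantity depends on age).
#' @return A genotype tibble in the [read_genotypes()] schema, validated.
#' @export
#' @examples
#' g <- generate_genotypes(default_study_design(), seed = 1)
#' nrow(g)
generate_genotypes <- function(design, seed = 1L, ages = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  cells <- design$cells
  blocks <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    n <- cell$n
    if (n == 0L) next
    freqs <- design$allele_freqs
    gf <- design$group_freqs[[cell$diagnosis]]
    if (!is.null(gf)) freqs[names(gf)] <- gf
    sub_seed <- as.integer((as.numeric(seed) * 127 + i) %% (2^31 - 1))
    blocks[[i]] <- with_local_seed(sub_seed, {
      sex <- c(rep("female", cell$n_female), rep("male", n - cell$n_female))
      g <- tibble(
        sample_id = NA_character_,
        sex = sex,
        diagnosis = cell$diagnosis,
        sa_status = cell$sa_status,
        rs111798998 = draw_diploid(n, freqs$rs111798998),
        rs4290270 = draw_diploid(n, freqs$rs4290270),
        rs7305115 = draw_diploid(n, freqs$rs7305115),
        HTTLPR = draw_diploid(n, freqs$HTTLPR),
        uVNTR = ifelse(sex == "female", draw_diploid(n, freqs$uVNTR),
                       sample(names(freqs$uVNTR), n, replace = TRUE,
                              prob = freqs$uVNTR))
      )
      if (ages && "age_mean" %in% names(cells) && !is.na(cell$age_mean)) {
        g$age <- round(pmax(18, rnorm(n, cell$age_mean, cell$age_sd)), 1)
      }
      g
    })
  }
  out <- dplyr::bind_rows(blocks)
  out$sample_id <- sprintf("S%04d", seq_len(nrow(out)))
  validate_genotypes(out)
  out
}
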