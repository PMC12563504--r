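#' Default functional-variant specifications
#'
#' Returns the five functional variants the model uses, with their
#' allele-specific expression fold-changes relative to the reference allele
#' (reference multiplier = 1):
#'
#' * `rs111798998` (*TPH2*): G allele raises mRNA expression about 3-fold.
#' * `rs7305115` (*TPH2*): A allele raises expression about 1.7-fold.
#' * `rs4290270` (*TPH2*): A allele lowers expression about 1.4-fold
#'   (multiplier 1/1.4).
#' * `HTTLPR` (*SLC6A4* 5-HTTLPR): L allele raises transporter mRNA about
#'   3-fold relative to S.
#' * `uVNTR` (*MAOA*, X-linked): 4R and 3.5R alleles raise expression 5- to
#'   6-fold; `maoa_high` (default 5.5, the midpoint) sets the multiplier.
#'   2R, 3R and 5R are treated as reference.
#'
#' @param overrides Optional named list, `variant_id -> named numeric vector`
#'   of allele multipliers, merged over the defaults (e.g.
#'   `list(uVNTR = c("4R" = 6))`).
#' @param maoa_high Multiplier for the high-expression MAOA uVNTR alleles
#'   (4R, 3.5R). Default 5.5.
#' @return A tibble with one row per variant-allele pair: `gene`,
#'   `variant_id`, `inheritance` (`"autosomal"` or `"x_linked"`), `allele`,
#'   `multiplier`, `reference`.
#' @export
#' @examples
#' default_variant_specs()
#' default_variant_specs(overrides = list(HTTLPR = c(L = 2.5)))
default_variant_specs <- function(overrides = NULL, maoa_high = 5.5) {
  stopifnot(is.numeric(maoa_high), length(maoa_high) == 1L, maoa_high > 0)
  specs <- dplyr::bind_rows(
    tibble(gene = "TPH2", variant_id = "rs111798998",
           inheritance = "autosomal",
           allele = c("A", "G"), multiplier = c(1, 3)),
    tibble(gene = "TPH2", variant_id = "rs4290270",
           inheritance = "autosomal",
           allele = c("T", "A"), multiplier = c(1, 1 / 1.4)),
    tibble(gene = "TPH2", variant_id = "rs7305115",
           inheritance = "autosomal",
           allele = c("G", "A"), multiplier = c(1, 1.7)),
    tibble(gene = "SLC6A4", variant_id = "HTTLPR",
           inheritance = "autosomal",
           allele = c("S", "L"), multiplier = c(1, 3)),
    tibble(gene = "MAOA", variant_id = "uVNTR",
           inheritance = "x_linked",
           allele = c("2R", "3R", "3.5R", "4R", "5R"),
           multiplier = c(1, 1, maoa_high, maoa_high, 1))
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (vid in names(overrides)) {
      ov <- overrides[[vid]]
      if (!vid %in% specs$variant_id) {
        abort(paste0("unknown variant in overrides: ", vid))
      }
      if (!is.numeric(ov) || is.null(names(ov))) {
        abort(paste0("override for ", vid,
                     " must be a named numeric vector of multipliers"))
      }
      bad <- setdiff(names(ov), specs$allele[specs$variant_id == vid])
      if (length(bad)) {
        abort(paste0("unknown allele(s) for ", vid, ": ",
                     paste(bad, collapse = ", ")))
      }
      idx <- match(paste(vid, names(ov)), paste(specs$variant_id, specs$allele))
      specs$multiplier[idx] <- unname(ov)
    }
  }
  specs$reference <- specs$multiplier == 1
  validate_variant_specs(specs)
  specs
}

#' Validate a variant-specification table
#'
#' Checks the structural invariants of a variant spec table: positive
#' multipliers, at least one reference allele (multiplier exactly 1) per
#' variant, unique alleles within a variant, and X-linked inheritance for the
#' MAOA uVNTR.
#'
#' @param specs A tibble as returned by [default_variant_specs()].
#' @return `specs`, invisibly, if valid; otherwise an error.
#' @export
validate_variant_specs <- function(specs) {
  need <- c("gene", "variant_id", "inheritance", "allele", "multiplier")
  if (!all(need %in% names(specs))) {
    abort(paste0("variant specs must have columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(!is.finite(specs$multiplier)) || any(specs$multiplier <= 0)) {
    abort("all allele multipliers must be finite and > 0")
  }
  by_var <- split(specs, specs$variant_id)
  for (sp in by_var) {
    if (anyDuplicated(sp$allele)) {
      abort(paste0("duplicate alleles in variant ", sp$variant_id[1]))
    }
    if (!any(sp$multiplier == 1)) {
      abort(paste0("variant ", sp$variant_id[1],
                   " has no reference allele (multiplier 1)"))
    }
    if (length(unique(sp$inheritance)) != 1L) {
      abort(paste0("inconsistent inheritance for ", sp$variant_id[1]))
    }
  }
  if ("uVNTR" %in% specs$variant_id &&
      any(specs$inheritance[specs$variant_id == "uVNTR"] != "x_linked")) {
    abort("MAOA uVNTR must be x_linked")
  }
  auto <- specs$variant_id != "uVNTR"
  if (any(specs$inheritance[auto] != "autosomal")) {
    abort("all variants except the MAOA uVNTR must be autosomal")
  }
  invisible(specs)
}

# Split "A/G" -> c("A","G"); bare "4R" -> "4R" (hemizygous).
split_call <- function(call) strsplit(call, "/", fixed = TRUE)[[1]]

#' Per-variant activity coefficient from one genotype call
#'
#' Converts a genotype call at a single variant into a dimensionless activity
#' multiplier. Diploid calls (`"A/G"`) combine the two allele multipliers by
#' their arithmetic mean (additive expression of the two gene copies);
#' hemizygous calls (a bare allele, as for the X-linked MAOA uVNTR in males)
#' use the single allele's multiplier.
#'
#' @param call Genotype call string: `"A1/A2"` for diploid, `"A1"` for
#'   hemizygous.
#' @param spec The rows of a variant-spec table (see
#'   [default_variant_specs()]) for one variant.
#' @return A single positive number.
#' @export
#' @examples
#' specs <- default_variant_specs()
#' variant_coefficient("L/S", dplyr::filter(specs, variant_id == "HTTLPR"))
variant_coefficient <- function(call, spec) {
  stopifnot(is.character(call), length(call) == 1L, !is.na(call))
  vid <- spec$variant_id[1]
  if (length(unique(spec$variant_id)) != 1L) {
    abort("spec must contain exactly one variant")
  }
  alleles <- split_call(call)
  if (!length(alleles) %in% 1:2) {
    abort(paste0("malformed call '", call, "' at ", vid))
  }
  idx <- match(alleles, spec$allele)
  if (anyNA(idx)) {
    abort(paste0("unknown allele '", alleles[which(is.na(idx))[1]],
                 "' at variant ", vid))
  }
  mean(spec$multiplier[idx])
}

#' Genotype-derived protein-activity coefficients
#'
#' Converts each individual's five-variant genotype into the activity
#' coefficient triple that scales the kinetic model: `c_tph2` (synthesis),
#' `c_sert` (reuptake) and `c_maoa` (degradation). Within a variant the two
#' allele multipliers are averaged ([variant_coefficient()]); across the three
#' *TPH2* variants the per-variant coefficients combine multiplicatively
#' (independent effects; haplotype phase is not modelled). The MAOA uVNTR is
#' X-linked: males contribute their single allele's multiplier, females the
#' mean of their two.
#'
#' @param genotypes A genotype tibble (see [read_genotypes()] for the schema):
#'   columns `sample_id`, `sex`, `diagnosis`, `sa_status` and one call column
#'   per variant.
#' @param specs Variant-spec table; defaults to [default_variant_specs()].
#' @return The input metadata columns plus `c_tph2`, `c_sert`, `c_maoa`, one
#'   row per sample.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   sample_id = "S1", sex = "female", diagnosis = "BD", sa_status = "SA",
#'   rs111798998 = "A/G", rs4290270 = "T/T", rs7305115 = "G/G",
#'   HTTLPR = "L/S", uVNTR = "3R/4R"
#' )
#' compute_activity(g)
compute_activity <- function(genotypes, specs = default_variant_specs()) {
  validate_variant_specs(specs)
  validate_genotypes(genotypes, specs)
  coef_one <- function(vid) {
    sp <- specs[specs$variant_id == vid, ]
    vapply(genotypes[[vid]], variant_coefficient, numeric(1), spec = sp,
           USE.NAMES = FALSE)
  }
  tph2 <- coef_one("rs111798998") * coef_one("rs4290270") *
    coef_one("rs7305115")
  out <- dplyr::select(genotypes, dplyr::any_of(
    c("sample_id", "sex", "diagnosis", "sa_status", "age")))
  out$c_tph2 <- tph2
  out$c_sert <- coef_one("HTTLPR")
  out$c_maoa <- coef_one("uVNTR")
  as_tibble(out)
}

#' Validate a genotype table
#'
#' Checks a genotype tibble against a variant-spec table: required columns,
#' unique sample ids, valid factor levels, valid alleles at every variant,
#' X-linked hemizygosity (males carry exactly one MAOA uVNTR allele, females
#' two), and the convention that `sa_status` is missing exactly for
#' unaffected individuals. Errors name the offending row and variant.
#'
#' @inheritParams compute_activity
#' @return `genotypes`, invisibly, if valid.
#' @export
validate_genotypes <- function(genotypes, specs = default_variant_specs()) {
  meta <- c("sample_id", "sex", "diagnosis", "sa_status")
  missing_cols <- setdiff(c(meta, unique(specs$variant_id)), names(genotypes))
  if (length(missing_cols)) {
    abort(paste0("genotype table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genotypes) == 0L) abort("genotype table is empty")
  dup <- genotypes$sample_id[duplicated(genotypes$sample_id)]
  if (length(dup)) {
    abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
  }
  if (!all(genotypes$sex %in% c("female", "male"))) {
    bad <- which(!genotypes$sex %in% c("female", "male"))[1]
    abort(paste0("row ", bad, ": sex must be 'female' or 'male'"))
  }
  if (!all(genotypes$diagnosis %in% DIAGNOSES)) {
    bad <- which(!genotypes$diagnosis %in% DIAGNOSES)[1]
    abort(paste0("row ", bad, ": diagnosis must be one of ",
                 paste(DIAGNOSES, collapse = ", ")))
  }
  sa <- genotypes$sa_status
  unaff <- genotypes$diagnosis == "UNAFFECTED"
  if (any(unaff & !is.na(sa))) {
    abort(paste0("row ", which(unaff & !is.na(sa))[1],
                 ": unaffected individuals must have sa_status NA"))
  }
  if (any(!unaff & (is.na(sa) | !sa %in% SA_LEVELS))) {
    abort(paste0("row ", which(!unaff & (is.na(sa) | !sa %in% SA_LEVELS))[1],
                 ": patients must have sa_status SA or NONSA"))
  }
  for (vid in unique(specs$variant_id)) {
    sp <- specs[specs$variant_id == vid, ]
    calls <- genotypes[[vid]]
    if (any(is.na(calls))) {
      abort(paste0("row ", which(is.na(calls))[1], ": missing call at ", vid))
    }
    parts <- strsplit(calls, "/", fixed = TRUE)
    n_all <- lengths(parts)
    if (sp$inheritance[1] == "x_linked") {
      male <- genotypes$sex == "male"
      if (any(male & n_all != 1L)) {
        abort(paste0("row ", which(male & n_all != 1L)[1], ": males must ",
                     "carry exactly one ", vid, " allele (hemizygous)"))
      }
      if (any(!male & n_all != 2L)) {
        abort(paste0("row ", which(!male & n_all != 2L)[1],
                     ": females must carry two ", vid, " alleles"))
      }
    } else if (any(n_all != 2L)) {
      abort(paste0("row ", which(n_all != 2L)[1],
                   ": diploid call expected at ", vid))
    }
    ok <- vapply(parts, function(a) all(a %in% sp$allele), logical(1))
    if (!all(ok)) {
      bad_row <- which(!ok)[1]
      bad_allele <- setdiff(parts[[bad_row]], sp$allele)[1]
      abort(paste0("row ", bad_row, ": unknown allele '", bad_allele,
                   "' at variant ", vid))
    }
  }
  invisible(genotypes)
}

#' Read a genotype table from disk
#'
#' Reads a delimited genotype table (TSV by default; CSV accepted) with
#' header `sample_id, sex, diagnosis, sa_status, rs111798998, rs4290270,
#' rs7305115, HTTLPR, uVNTR`. Diploid calls are written `A1/A2`, hemizygous
#' calls as a bare allele. The literal string `NA` is interpreted as missing
#' only in `sa_status` (unaffected individuals) and `age`.
#'
#' @param path File path.
#' @param specs Variant-spec table used for validation.
#' @return A validated genotype tibble.
#' @export
read_genotypes <- function(path, specs = default_variant_specs()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  g <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  g$sa_status[g$sa_status == "NA"] <- NA_character_
  if ("age" %in% names(g)) {
    g$age[g$age == "NA"] <- NA_character_
    g$age <- as.numeric(g$age)
  }
  validate_genotypes(g, specs)
  g
}

#' Write a genotype table to disk
#'
#' Inverse of [read_genotypes()]: tab-separated (or comma-separated when the
#' path ends in `.csv`), `NA` written literally for missing `sa_status`.
#'
#' @param genotypes Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  readr::write_delim(genotypes, path, delim = delim, na = "NA",
                     progress = FALSE)
  invisible(path)
}

#' Enumerate all reachable activity-coefficient triples
#'
#' Enumerates every activity-coefficient triple `(c_tph2, c_sert, c_maoa)`
#' that any genotype can produce under a variant-spec table: all diploid
#' genotypes at the three *TPH2* variants and at 5-HTTLPR, and all MAOA uVNTR
#' calls (hemizygous male calls and diploid female calls). Used for
#' exhaustive property checks (non-negativity, mass balance, monotonicity)
#' and as the simulation grid for feature caching.
#'
#' @param specs Variant-spec table.
#' @return A tibble with columns `c_tph2`, `c_sert`, `c_maoa`, one row per
#'   distinct triple.
#' @export
enumerate_activity_grid <- function(specs = default_variant_specs()) {
  validate_variant_specs(specs)
  diplo <- function(vid) {
    sp <- specs[specs$variant_id == vid, ]
    m <- sp$multiplier
    unique(as.vector(outer(m, m, function(a, b) (a + b) / 2)))
  }
  c_tph2 <- unique(as.vector(outer(
    as.vector(outer(diplo("rs111798998"), diplo("rs4290270"))),
    diplo("rs7305115"))))
  c_sert <- diplo("HTTLPR")
  sp_m <- specs[specs$variant_id == "uVNTR", ]
  c_maoa <- unique(c(sp_m$multiplier, diplo("uVNTR")))
  tidyr::expand_grid(c_tph2 = sort(c_tph2), c_sert = sort(c_sert),
                     c_maoa = sort(c_maoa))
}
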