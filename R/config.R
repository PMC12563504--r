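#' Read a run configuration file
#'
#' Reads a YAML or JSON configuration with any of the sections:
#'
#' * `kinetics`: named overrides for [kinetic_defaults()].
#' * `variants`: `variant_id -> allele -> multiplier` overrides for
#'   [default_variant_specs()].
#' * `cohort`: `cells` (list of cell rows), `allele_freqs`, `group_freqs`
#'   for [cohort_design()].
#' * `statistics`: `posthoc`, `bh` flags for [run_presynapse_analysis()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `specs`, `params`, `design` (each `NULL`
#'   when its section is absent) and `statistics` (a list, possibly empty),
#'   plus the raw parsed config as `"raw"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config must be .yaml/.yml or .json")
  }
  specs <- NULL
  if (!is.null(raw$variants)) {
    ov <- lapply(raw$variants, function(v) unlist(v))
    specs <- default_variant_specs(overrides = ov)
  }
  params <- NULL
  if (!is.null(raw$kinetics)) {
    params <- do.call(kinetic_defaults, as.list(raw$kinetics))
  }
  design <- NULL
  if (!is.null(raw$cohort)) {
    co <- raw$cohort
    cells <- if (is.data.frame(co$cells)) as_tibble(co$cells) else
      dplyr::bind_rows(lapply(co$cells, as_tibble))
    if ("sa_status" %in% names(cells)) {
      cells$sa_status[cells$sa_status == "NA"] <- NA_character_
    }
    af <- if (is.null(co$allele_freqs)) default_allele_freqs() else
      lapply(co$allele_freqs, unlist)
    gf <- if (is.null(co$group_freqs)) NULL else
      lapply(co$group_freqs, function(g) lapply(g, unlist))
    design <- cohort_design(cells, af, gf)
  }
  list(specs = specs, params = params, design = design,
       statistics = raw$statistics %||% list(), raw = raw)
}
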