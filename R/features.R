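#' Six summary statistics of one concentration series
#'
#' Summarises a sampled time series by its mean, median, maximum, standard
#' deviation, skewness and kurtosis. Moments are population (biased) central
#' moments: `sd = sqrt(m2)`, `skew = m3 / m2^1.5`, `kurt = m4 / m2^2`
#' (Pearson, non-excess; a normal series has kurtosis 3). Optionally the
#' sample-corrected estimators and/or excess kurtosis can be requested.
#' Degenerate (constant) series have `m2 = 0`; they return skewness and
#' kurtosis 0 with `degenerate = TRUE` rather than NaN so downstream rank
#' tests stay total.
#'
#' @param x Non-empty numeric vector, all finite.
#' @param type `"population"` (default) or `"sample"` (bias-corrected
#'   skewness/kurtosis, `sd` with `n - 1` denominator).
#' @param excess If `TRUE`, report excess kurtosis (`kurt - 3` under the
#'   population convention).
#' @return A one-row tibble: `mean`, `median`, `max`, `sd`, `skew`, `kurt`,
#'   `degenerate`.
#' @export
#' @examples
#' summarize_series(c(1, 2, 3, 4))
summarize_series <- function(x, type = c("population", "sample"),
                             excess = FALSE) {
  type <- match.arg(type)
  if (length(x) == 0L) abort("empty series")
  if (anyNA(x) || any(!is.finite(x))) abort("non-finite value in series")
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  degenerate <- m2 == 0
  if (degenerate) {
    sdv <- 0; skew <- 0; kurt <- 0
  } else if (type == "population") {
    sdv <- sqrt(m2)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    sdv <- sqrt(m2 * n / (n - 1))
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    skew <- if (n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
    kurt <- if (n > 3) {
      (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * g2 + 6) + 3
    } else m4 / m2^2
  }
  if (excess && !degenerate) kurt <- kurt - 3
  tibble(mean = mu, median = median(x), max = max(x), sd = sdv,
         skew = skew, kurt = kurt, degenerate = degenerate)
}

#' Thirty model-derived features from simulated trajectories
#'
#' Applies [summarize_series()] to each of the five reported molecular
#' species of each sample's trajectory, yielding the 30-feature row per
#' individual (`<species>_<stat>`, species in order `htp, fc5ht, v5ht, e5ht,
#' hiaa`, statistics in order `mean, median, max, sd, skew, kurt`). All
#' trajectories must share an identical time grid.
#'
#' @param trajectories Either a tidy long tibble with columns `sample_id`,
#'   `time_min`, `species`, `concentration_uM` (see [tidy_trajectory()]), or
#'   a named list of `"presynapse_trajectory"` tibbles keyed by sample id.
#' @param type,excess Moment conventions passed to [summarize_series()].
#' @return A tibble: `sample_id` plus 30 feature columns, one row per sample,
#'   in input order.
#' @export
#' @examples
#' traj <- simulate_trajectory(params = kinetic_defaults(t_end = 60))
#' extract_features(list(S1 = traj))
extract_features <- function(trajectories, type = "population",
                             excess = FALSE) {
  if (is.data.frame(trajectories)) {
    need <- c("sample_id", "time_min", "species", "concentration_uM")
    if (!all(need %in% names(trajectories))) {
      abort(paste0("long trajectory table must have columns: ",
                   paste(need, collapse = ", ")))
    }
    long <- trajectories
    long$species <- as.character(long$species)
    bad <- setdiff(unique(long$species), SPECIES)
    if (length(bad)) {
      abort(paste0("unknown species: ", paste(bad, collapse = ", ")))
    }
    ids <- unique(long$sample_id)
    grids <- split(long$time_min, list(long$sample_id, long$species),
                   drop = TRUE)
    ref <- grids[[1]]
    same <- vapply(grids, function(g) identical(length(g), length(ref)) &&
                     all(g == ref), logical(1))
    if (!all(same)) abort("trajectories are not on identical time grids")
    rows <- lapply(ids, function(id) {
      sub <- long[long$sample_id == id, ]
      feature_row(split(sub$concentration_uM, sub$species), type, excess)
    })
  } else if (is.list(trajectories)) {
    if (length(trajectories) == 0L) abort("no trajectories supplied")
    ids <- names(trajectories) %||% as.character(seq_along(trajectories))
    ref <- trajectories[[1]]$time_min
    rows <- lapply(trajectories, function(tr) {
      missing_cols <- setdiff(c("time_min", SPECIES), names(tr))
      if (length(missing_cols)) {
        abort(paste0("trajectory lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
      }
      if (length(tr$time_min) != length(ref) || !all(tr$time_min == ref)) {
        abort("trajectories are not on identical time grids")
      }
      feature_row(as.list(tr[SPECIES]), type, excess)
    })
  } else {
    abort("trajectories must be a long tibble or a named list of trajectories")
  }
  dplyr::bind_cols(tibble(sample_id = ids), dplyr::bind_rows(rows))
}

feature_row <- function(series_by_species, type, excess) {
  vals <- lapply(SPECIES, function(sp) {
    st <- summarize_series(series_by_species[[sp]], type = type,
                           excess = excess)
    setNames(as.numeric(st[1, STATS]), paste0(sp, "_", STATS))
  })
  as_tibble(as.list(unlist(vals)))
}

#' Simulate a cohort and extract its feature matrix
#'
#' Runs the kinetic model for every individual in an activity table and
#' returns the 30-feature matrix. Trajectories depend on genotype only
#' through the coefficient triple `(c_tph2, c_sert, c_maoa)`, which takes
#' few distinct values in a cohort, so the ODE is integrated once per
#' distinct triple and the features are joined back onto samples. A
#' precomputed `feature_cache` (see [build_feature_cache()]) skips even
#' those integrations.
#'
#' @param activity Tibble from [compute_activity()]: `sample_id`, metadata,
#'   `c_tph2`, `c_sert`, `c_maoa`.
#' @param params Kinetic parameters ([kinetic_defaults()]).
#' @param feature_cache Optional tibble from [build_feature_cache()] with
#'   columns `c_tph2`, `c_sert`, `c_maoa` and the 30 features, computed under
#'   the same `params`. Triples absent from the cache are simulated.
#' @return `activity`'s metadata columns plus the 30 feature columns.
#' @export
#' @examples
#' g <- generate_genotypes(default_study_design(), seed = 1)
#' act <- compute_activity(g[1:5, ])
#' simulate_features(act, kinetic_defaults(t_end = 60))
simulate_features <- function(activity, params = kinetic_defaults(),
                              feature_cache = NULL) {
  need <- c("sample_id", "c_tph2", "c_sert", "c_maoa")
  missing_cols <- setdiff(need, names(activity))
  if (length(missing_cols)) {
    abort(paste0("activity table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  key <- c("c_tph2", "c_sert", "c_maoa")
  triples <- dplyr::distinct(activity[, key])
  if (!is.null(feature_cache)) {
    triples <- dplyr::anti_join(triples, feature_cache, by = key)
  }
  computed <- if (nrow(triples)) {
    feats <- purrr::pmap(triples, function(c_tph2, c_sert, c_maoa) {
      tr <- simulate_trajectory(c_tph2, c_sert, c_maoa, params)
      feature_row(as.list(tr[SPECIES]), "population", FALSE)
    })
    dplyr::bind_cols(triples, dplyr::bind_rows(feats))
  } else {
    NULL
  }
  lookup <- dplyr::bind_rows(feature_cache, computed)
  dplyr::left_join(as_tibble(activity), lookup, by = key)
}

#' Precompute features for every reachable coefficient triple
#'
#' Integrates the kinetic model once for each activity-coefficient triple in
#' [enumerate_activity_grid()] (or a supplied grid) and returns a lookup
#' table usable as `feature_cache` in [simulate_features()]. Useful when many
#' cohorts are simulated under the same kinetic parameters (power and
#' calibration studies).
#'
#' @param specs Variant-spec table defining the reachable triples.
#' @param params Kinetic parameters.
#' @param grid Optional explicit tibble of triples (overrides `specs`).
#' @return Tibble: `c_tph2`, `c_sert`, `c_maoa` plus the 30 features.
#' @export
build_feature_cache <- function(specs = default_variant_specs(),
                                params = kinetic_defaults(),
                                grid = NULL) {
  grid <- grid %||% enumerate_activity_grid(specs)
  feats <- purrr::pmap(grid[, c("c_tph2", "c_sert", "c_maoa")],
                       function(c_tph2, c_sert, c_maoa) {
    tr <- simulate_trajectory(c_tph2, c_sert, c_maoa, params)
    feature_row(as.list(tr[SPECIES]), "population", FALSE)
  })
  dplyr::bind_cols(as_tibble(grid), dplyr::bind_rows(feats))
}
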