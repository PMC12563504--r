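#' Plot simulated concentration trajectories
#'
#' Concentration-vs-time curves for the reported molecular species of one or
#' more simulated individuals.
#'
#' @param trajectories A single `"presynapse_trajectory"`, a named list of
#'   them, or a tidy long tibble from [tidy_trajectory()].
#' @param species Species to show (default all five reported).
#' @return A ggplot object.
#' @export
#' @examples
#' traj <- simulate_trajectory(params = kinetic_defaults(t_end = 120))
#' plot_trajectories(traj)
plot_trajectories <- function(trajectories, species = SPECIES) {
  if (inherits(trajectories, "presynapse_trajectory")) {
    long <- tidy_trajectory(trajectories, sample_id = "sample",
                            species = species)
  } else if (is.data.frame(trajectories)) {
    long <- trajectories
  } else {
    ids <- names(trajectories) %||% as.character(seq_along(trajectories))
    long <- purrr::map2_dfr(trajectories, ids, function(tr, id) {
      tidy_trajectory(tr, sample_id = id, species = species)
    })
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                     y = .data$concentration_uM,
                                     colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (µM)",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' @export
#' @rdname plot_trajectories
#' @param object,... For `autoplot`: a trajectory and arguments passed on.
autoplot.presynapse_trajectory <- function(object, ...) {
  plot_trajectories(object, ...)
}

#' Interaction plot for one model-derived feature
#'
#' Cell means with standard-error bars of one feature across diagnosis,
#' split by suicide-attempt status - the standard visual companion of the
#' two-way ART ANOVA interaction test.
#'
#' @param features Feature tibble with `diagnosis`, `sa_status` and the
#'   feature columns (patients only are shown).
#' @param feature Feature column name (string), e.g. `"hiaa_skew"`.
#' @return A ggplot object.
#' @export
plot_feature_interaction <- function(features, feature) {
  if (!feature %in% names(features)) {
    abort(paste0("no such feature column: ", feature))
  }
  d <- features[features$diagnosis != "UNAFFECTED" &
                  !is.na(features$sa_status), ]
  cell <- d |>
    dplyr::group_by(.data$diagnosis, .data$sa_status) |>
    dplyr::summarise(
      m = mean(.data[[feature]]),
      se = stats::sd(.data[[feature]]) / sqrt(dplyr::n()),
      .groups = "drop")
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$diagnosis, y = .data$m,
                                     colour = .data$sa_status,
                                     group = .data$sa_status)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      width = 0.15, position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::labs(x = "diagnosis", y = feature, colour = "SA status") +
    ggplot2::theme_minimal()
}
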