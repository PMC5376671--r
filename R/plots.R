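#' Space-time and population plots for tissue simulations
#'
#' `autoplot.tissue_result()` draws a space-time (development) or
#' population-time (differentiation) heat map of one species, averaging
#' over replicates.
#'
#' @param object A `tissue_result`.
#' @param species Species to display (default `"hoxa5_protein"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue_result <- function(object, species = "hoxa5_protein", ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$species == !!species) |>
    dplyr::summarise(
      value = mean(.data$value),
      .by = c("position", "time")
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$position,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = species) +
    ggplot2::labs(
      x = "time (days)",
      y = if (object$protocol == "development") {
        "rostrocaudal position"
      } else {
        "cell"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot occupancy profiles of a boundary report
#'
#' Shows, for Hoxa5 and Hoxc8 protein, the fraction of replicates calling
#' each position "expressing", with the 15%/85% transition-zone bounds.
#'
#' @param report A [boundary_report()].
#' @param lo,hi Occupancy bounds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(report, lo = 0.15, hi = 0.85) {
  profiles <- attr(report, "profiles")
  if (is.null(profiles)) stop("report carries no profiles", call. = FALSE)
  ggplot2::ggplot(profiles, ggplot2::aes(.data$position, .data$occupancy,
    colour = .data$species
  )) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = c(lo, hi), linetype = "dashed",
      colour = "grey50"
    ) +
    ggplot2::scale_colour_manual(values = c(
      hoxa5_protein = "#c23b22", hoxc8_protein = "#2e7d32"
    )) +
    ggplot2::labs(x = "rostrocaudal position", y = "occupancy") +
    ggplot2::theme_minimal()
}

#' @describeIn autoplot.tissue_result Score distribution of a topology
#'   screen; topologies carrying all consensus interactions are
#'   highlighted.
#' @export
autoplot.screen_result <- function(object, ...) {
  cons <- consensus_interactions(object)
  df <- tidy(object)
  df$has_consensus <- if (nrow(cons) == 0L) {
    rep(FALSE, nrow(df))
  } else {
    purrr::pmap_lgl(
      df[cons$edge],
      function(...) all(c(...) == cons$value)
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$mean_score,
    colour = .data$has_consensus
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c23b22", `FALSE` = "grey60"),
      name = "all consensus edges"
    ) +
    ggplot2::labs(x = "rank", y = "mean robustness score") +
    ggplot2::theme_minimal()
}
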