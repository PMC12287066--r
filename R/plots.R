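#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the preprocessing stages of a channel
#'
#' Stacked panels of raw, filtered (+ fitted isosbestic baseline), DF/F
#' and Z-score traces for one processed channel.
#'
#' @param object A `ph_channel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ph_channel <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("raw", "filtered", "fitted", "dff", "zscore"),
                        names_to = "stage", values_to = "value") |>
    dplyr::mutate(stage = factor(.data$stage,
                                 levels = c("raw", "filtered", "fitted", "dff", "zscore")))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value, colour = .data$stage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(
      title = sprintf("Channel %s", attr(object, "role")),
      x = "time (s)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot an onset-locked ensemble
#'
#' Mean Z-score with a ±SEM ribbon against relative time; the vertical
#' line marks event onset ("time point 0").
#'
#' @param object A `ph_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ph_ensemble <- function(object, ...) {
  df <- ensemble_mean(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_time, .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event onset (s)", y = "Z-score (mean ± SEM)") +
    ggplot2::theme_minimal()
}

#' Plot a spatial signal map
#'
#' Raster of the occupancy map or the occupancy-normalized signal map
#' over the board-normalized grid; unvisited bins are blank.
#'
#' @param object A `ph_maps`.
#' @param which `"signal_norm"`, `"occupancy"` or `"signal_sum"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ph_maps <- function(object, which = "signal_norm", ...) {
  df <- tidy(object)
  df$value <- df[[which]]
  if (which != "signal_norm") df$value[!df$visited] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mid, .data$y_mid, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = which) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "board x", y = "board y") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory on the normalized board
#'
#' @param traj A `ph_traj`.
#' @param zone Optional `ph_zone` to outline.
#' @return A ggplot object.
#' @export
plot_trackmap <- function(traj, zone = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(traj, !.data$gap),
                       ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(alpha = 0.5, colour = "grey30") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "board x", y = "board y") +
    ggplot2::theme_minimal()
  if (!is.null(zone) && zone$kind == "disc") {
    th <- seq(0, 2 * pi, length.out = 100)
    circ <- tibble(
      x = zone$center[1] + zone$radius * cos(th),
      y = zone$center[2] + zone$radius * sin(th)
    )
    p <- p + ggplot2::geom_path(data = circ, colour = "red")
  }
  p
}
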