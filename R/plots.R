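#' Plot a fractional-volume density map
#'
#' @param density a `san_density_map` from [fractional_volume_map()].
#' @return A ggplot heat map (tile rows along the node axis).
#' @export
plot_density_map <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(.data$tile_col, .data$tile_row,
                                        fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "fractional\nvolume") +
    ggplot2::labs(x = "tile column", y = "tile row (superior at top)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.san_boundary_fit <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(.data$row, .data$mean_um)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_um - .data$sem_um,
                   ymax = .data$mean_um + .data$sem_um),
      fill = "grey80"
    ) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "row (superior to inferior)",
                  y = "myocyte-to-vessel distance (um)") +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    fit_df <- tibble::tibble(row = prof$row, fitted = {
      par <- object$fit$parameters
      par["lower"] + (par["upper"] - par["lower"]) /
        (1 + exp(-par["k"] * (prof$row - par["x0"])))
    })
    p <- p +
      ggplot2::geom_line(data = fit_df,
                         ggplot2::aes(.data$row, .data$fitted),
                         colour = "steelblue", linewidth = 1) +
      ggplot2::geom_vline(xintercept = object$boundary_row,
                          linetype = "dashed", colour = "steelblue")
  }
  p
}

#' @export
autoplot.san_mixture <- function(object, data = NULL, bins = 30, ...) {
  comp <- tidy(object)
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(x = data),
      ggplot2::aes(.data$x, ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60"
    )
    xs <- seq(min(data), max(data), length.out = 400)
  } else {
    xs <- seq(min(comp$center - 4 * comp$width),
              max(comp$center + 4 * comp$width), length.out = 400)
  }
  dens <- lapply(seq_len(nrow(comp)), function(j) {
    tibble::tibble(
      x = xs, component = factor(j),
      density = comp$weight[j] * dnorm(xs, comp$center[j], comp$width[j])
    )
  })
  dens <- dplyr::bind_rows(dens)
  p +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(.data$x, .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(
      data = dplyr::summarise(dplyr::group_by(dens, .data$x),
                              density = sum(.data$density), .groups = "drop"),
      ggplot2::aes(.data$x, .data$density), colour = "black"
    ) +
    ggplot2::labs(x = "amplitude", y = "density") +
    ggplot2::theme_minimal()
}

#' Joint inter-event interval plot
#'
#' Scatter of each inter-event interval against the next; tight clusters
#' indicate tonic firing, diffuse clouds irregular firing, and "L-shaped"
#' distributions bursting.
#'
#' @param stats a [interval_stats()] result.
#' @return A ggplot.
#' @export
plot_joint_intervals <- function(stats) {
  ggplot2::ggplot(stats$joint, ggplot2::aes(.data$isi_ms, .data$next_isi_ms)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "inter-event interval i (ms)",
                  y = "inter-event interval i+1 (ms)") +
    ggplot2::theme_minimal()
}

#' Kymograph image with optional spark overlay
#'
#' @param kymo a [san_kymo()].
#' @param sparks optional spark table to overlay.
#' @return A ggplot raster of the kymograph.
#' @export
plot_kymograph <- function(kymo, sparks = NULL) {
  df <- expand.grid(
    position_um = (seq_len(nrow(kymo$fluor)) - 0.5) * kymo$pixel_um,
    time_s = (seq_len(ncol(kymo$fluor)) - 0.5) * kymo$line_interval_ms / 1000
  )
  df$value <- as.vector(kymo$fluor)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$position_um,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (kymo$normalized) "dF/F0" else "F"
    ) +
    ggplot2::labs(x = "time (s)", y = "position (um)") +
    ggplot2::theme_minimal()
  if (!is.null(sparks) && nrow(sparks) > 0) {
    p <- p + ggplot2::geom_point(
      data = sparks,
      ggplot2::aes(.data$time_s, .data$position_um),
      inherit.aes = FALSE, colour = "red", shape = 1, size = 2
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
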