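#' Plot an impulse response waveform
#'
#' @param object An `impulse_response`.
#' @param envelope Overlay the analytic-signal envelope (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.impulse_response <- function(object, envelope = TRUE, ...) {
  df <- tidy.impulse_response(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1e3)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$amplitude), linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "amplitude",
                  title = "Foliage echo impulse response")
  if (envelope) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$envelope),
                                colour = "red", alpha = 0.6)
  }
  p
}

#' Plot an echo spectrum magnitude
#'
#' @param object An `echo_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.echo_spectrum <- function(object, ...) {
  df <- tibble::tibble(f = object$f / 1e3,
                       magnitude = sqrt(object$re^2 + object$im^2))
  ggplot2::ggplot(df, ggplot2::aes(.data$f, .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (kHz)", y = "|y*|",
                  title = "Echo spectrum magnitude")
}

#' Plot a branch skeleton in side view
#'
#' @param object A `branch_skeleton`.
#' @param ... Unused.
#' @return A ggplot (x-z projection, segment width scaled by radius).
#' @export
autoplot.branch_skeleton <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$z0, xend = .data$x1, yend = .data$z1,
                   linewidth = .data$radius_start),
      lineend = "round", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)", title = "Branch skeleton")
}

#' Plot a tree: skeleton plus leaf discs
#'
#' @param object A `sim_tree`.
#' @param ... Unused.
#' @return A ggplot (x-z projection; leaves as green points).
#' @export
autoplot.sim_tree <- function(object, ...) {
  autoplot.branch_skeleton(object$skeleton) +
    ggplot2::geom_point(
      data = object$leaf_discs,
      ggplot2::aes(x = .data$x, y = .data$z, size = .data$radius),
      colour = "forestgreen", alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(title = sprintf("Simulated tree (%s)", object$species))
}

#' Plot forest tree locations
#'
#' @param object A `sim_forest`.
#' @param ... Unused.
#' @return A ggplot of tree locations coloured by species.
#' @export
autoplot.sim_forest <- function(object, ...) {
  ggplot2::ggplot(tidy.sim_forest(object),
                  ggplot2::aes(.data$x, .data$y, colour = .data$species,
                               size = .data$n_leaf_discs)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Forest tree locations")
}

#' Plot per-pose scenario echoes
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot faceted by pose.
#' @export
autoplot.scenario_result <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i) {
    ir <- object$ir[[i]]
    tibble::tibble(pose = object$pose[i], time = ir$time,
                   amplitude = ir$amplitude,
                   label = sprintf("pose %d (m = %d, %.0f deg)",
                                   object$pose[i], object$m[i],
                                   object$beamwidth_deg[i]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time * 1e3, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "amplitude",
                  title = "Impulse responses along the trajectory")
}

#' Raster plot of a point-process intensity
#'
#' @param mixture An [intensity_mixture()].
#' @param n Grid resolution per axis.
#' @param points Optional tibble of sampled locations to overlay.
#' @return A ggplot.
#' @export
plot_intensity <- function(mixture, n = 200, points = NULL) {
  d <- mixture$domain
  g <- expand.grid(x = seq(d[1], d[2], length.out = n),
                   y = seq(d[3], d[4], length.out = n))
  g$lambda <- intensity(mixture, g$x, g$y)
  p <- ggplot2::ggplot(g, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$lambda)) +
    ggplot2::scale_fill_viridis_c(name = expression(lambda)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = "Point-process intensity")
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, colour = "white", size = 0.8)
  }
  p
}
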