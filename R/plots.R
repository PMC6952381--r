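## ggplot2 display methods.

#' Plot a radial scattering pattern
#'
#' @param object a `cross_section_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cross_section_result
#' @export
autoplot.cross_section_result <- function(object, ...) {
  ggplot2::ggplot(object$pattern,
                  ggplot2::aes(x = .data$q_nm_inv,
                               y = .data$dsdo_barn_sr)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (nm^-1)),
                  y = expression(d * sigma / d * Omega ~ (barn / sr)),
                  title = sprintf("%s scattering pattern",
                                  if (isTRUE(object$damaged)) "Damaged"
                                  else "Undamaged")) +
    ggplot2::theme_minimal()
}

#' Plot the ionization/expansion history of a trajectory
#'
#' @param object a `cluster_trajectory`.
#' @param ... unused.
#' @return a ggplot (electron bookkeeping and diameter vs time).
#' @method autoplot cluster_trajectory
#' @export
autoplot.cluster_trajectory <- function(object, ...) {
  cen <- trajectory_census(object)
  long <- tidyr::pivot_longer(
    cen[, c("t_fs", "n_delocalized", "escaped", "bound_electrons",
            "diameter_nm")],
    -"t_fs", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_fs, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "t (fs)", y = NULL,
                  title = "Cluster dynamics census") +
    ggplot2::theme_minimal()
}

#' Plot a detector image
#'
#' @param image photon-count matrix.
#' @param geometry a [detector_geometry()].
#' @param log_scale log10 colour scale.
#' @return a ggplot raster of the image.
#' @export
plot_image <- function(image, geometry, log_scale = TRUE) {
  df <- tibble::tibble(
    x = as.vector(geometry$x_mm),
    y = as.vector(geometry$y_mm),
    counts = as.vector(image))
  if (log_scale) df$counts <- log10(df$counts + 0.1)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$counts)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(
      name = if (log_scale) "log10(counts)" else "counts") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' Plot a radial profile with an optional fitted sphere model
#'
#' @param image photon-count matrix.
#' @param geometry a [detector_geometry()].
#' @param fit optional [fit_sphere()] result to overlay.
#' @param n_bins radial bins.
#' @return a ggplot.
#' @export
plot_radial_fit <- function(image, geometry, fit = NULL, n_bins = 180) {
  prof <- radial_profile(image, geometry, n_bins)
  g <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$theta,
                                          y = .data$mean_counts)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(theta ~ (rad)),
                  y = "mean photons / pixel") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    shape <- .profile_shape(fit$d_nm, fit$wavelength_nm,
                            fit$delta_n_abs, prof) * fit$i0_photons_nm2
    g <- g + ggplot2::geom_line(
      data = tibble::tibble(theta = prof$theta, model = shape),
      ggplot2::aes(x = .data$theta, y = .data$model),
      colour = "red")
  }
  g
}

#' Plot a charge-state distribution
#'
#' @param dist tibble from [argon_benchmark()] (`charge`, `probability`).
#' @return a ggplot bar chart.
#' @export
plot_charge_states <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = factor(.data$charge),
                                     y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "final charge state", y = "probability") +
    ggplot2::theme_minimal()
}
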