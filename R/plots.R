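#' Plot a biplane calibration curve
#'
#' FWHM of both channels versus depth; the crossing point marks the midpoint
#' between the two focal planes.
#'
#' @param object A `calibration_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("fwhm_h_nm", "fwhm_v_nm"),
                            names_to = "channel", values_to = "fwhm_nm")
  df$channel <- ifelse(df$channel == "fwhm_h_nm", "H (channel A)",
                       "V (channel B)")
  ggplot2::ggplot(df, ggplot2::aes(.data$z_nm, .data$fwhm_nm,
                                   color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "FWHM (nm)", color = NULL,
                  title = "Biplane calibration") +
    ggplot2::theme_minimal()
}

#' Plot an FRC curve
#'
#' Ring-averaged Fourier correlation versus spatial frequency with the 1/7
#' threshold and the resolution crossing marked.
#'
#' @param object An `frc_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot frc_result
#' @export
autoplot.frc_result <- function(object, ...) {
  df <- object$curve
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq_per_nm, .data$frc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "spatial frequency (1/nm)", y = "FRC",
                  title = sprintf("FRC resolution %.1f nm", object$resolution_nm)) +
    ggplot2::theme_minimal()
  if (object$crossed)
    p <- p + ggplot2::geom_vline(xintercept = 1 / object$resolution_nm,
                                 linetype = 3)
  p
}

#' Scatter plot of localizations colored by spectral centroid
#'
#' @param locs Localization tibble.
#' @param color Column mapped to color (default spectral centroid).
#' @return A ggplot.
#' @export
plot_localizations <- function(locs, color = "lambda_c_nm") {
  if ("valid" %in% names(locs)) locs <- locs[locs$valid, ]
  ggplot2::ggplot(locs, ggplot2::aes(.data$x_nm, .data$y_nm,
                                     color = .data[[color]])) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a precision sweep
#'
#' One panel per method, precision per axis versus the swept variable.
#'
#' @param sweep Output of [run_precision_sweep()].
#' @return A ggplot.
#' @export
plot_precision_sweep <- function(sweep) {
  df <- tidyr::pivot_longer(sweep, c("sigma_x_nm", "sigma_y_nm"),
                            names_to = "axis", values_to = "sigma_nm")
  df$axis <- ifelse(df$axis == "sigma_x_nm", "x", "y")
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$sigma_nm,
                                   color = .data$axis)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = unique(df$vary), y = "precision (nm)", color = "axis") +
    ggplot2::theme_minimal()
}

#' Plot a crosstalk sweep
#'
#' @param sweep Output of [run_crosstalk_sweep()].
#' @return A ggplot.
#' @export
plot_crosstalk_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$dispersion_nm_per_px,
                                      .data$crosstalk_pct,
                                      color = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dispersion (nm/pixel)", y = "crosstalk (%)",
                  color = NULL) +
    ggplot2::theme_minimal()
}
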