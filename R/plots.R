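# ggplot2 autoplot methods for the package's result objects

#' Plot a super-resolved density image
#'
#' @param object A `spaint_image` from [render_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spaint_image <- function(object, ...) {
  df <- tibble::as_tibble(expand.grid(
    y = seq_len(nrow(object$density)), x = seq_len(ncol(object$density))))
  df$density <- as.vector(object$density)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("x (%g nm px)", object$pixel_nm),
                  y = "y", fill = "density") +
    ggplot2::theme_minimal()
}

#' Plot a false-coloured sPAINT render
#'
#' @param object A `spaint_render` from [render_spaint()].
#' @param ... Unused.
#' @return A ggplot object showing the RGB overlay.
#' @export
autoplot.spaint_render <- function(object, ...) {
  ny <- dim(object$rgb)[1]; nx <- dim(object$rgb)[2]
  ggplot2::ggplot() +
    ggplot2::annotation_raster(object$rgb, xmin = 0, xmax = nx,
                               ymin = -ny, ymax = 0) +
    ggplot2::xlim(0, nx) + ggplot2::ylim(-ny, 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("x (%g nm px)", object$pixel_nm), y = "y") +
    ggplot2::theme_void()
}

#' Plot a spectral frequency histogram
#'
#' @param object A `spaint_spectral_hist` from [spectral_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spaint_spectral_hist <- function(object, ...) {
  occupied <- which(object$histogram$count > 0)
  rng <- range(object$histogram$wavelength_nm[occupied])
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$wavelength_nm, .data$count)) +
    ggplot2::geom_col(width = diff(object$histogram$wavelength_nm[1:2]),
                      fill = "grey30") +
    ggplot2::coord_cartesian(xlim = rng + c(-10, 10)) +
    ggplot2::labs(x = "emission peak (nm)", y = "frequency",
                  subtitle = sprintf("mean %.1f nm, sd %.1f nm, n = %d",
                                     object$mean_nm, object$sd_nm,
                                     object$n)) +
    ggplot2::theme_minimal()
}

#' Plot an empirical precision curve with its asymptote fit
#'
#' @param object A `spaint_precision_fit` from [bin_and_fit()] or
#'   [precision_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spaint_precision_fit <- function(object, ...) {
  grid <- tibble::tibble(
    bin_center = seq(min(object$curve$bin_center),
                     max(object$curve$bin_center), length.out = 200))
  grid$fit <- predict(object$fit, newdata = grid)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$bin_center, .data$mean_sigma_nm)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "red") +
    ggplot2::geom_hline(yintercept = object$sigma_inf_nm,
                        linetype = "dashed") +
    ggplot2::labs(x = "photons", y = "precision (nm)",
                  subtitle = sprintf("sigma_inf = %.2f +/- %.2f nm",
                                     object$sigma_inf_nm,
                                     object$sigma_inf_se_nm)) +
    ggplot2::theme_minimal()
}

#' Plot calibration residuals against wavelength
#'
#' @param object A `spaint_calibration` from [calibrate_stack()].
#' @param ... Unused.
#' @return A ggplot object of recovered versus reference wavelength.
#' @export
autoplot.spaint_calibration <- function(object, ...) {
  if (is.null(object$measurements)) {
    stop("calibration carries no per-peak measurements to plot",
         call. = FALSE)
  }
  ggplot2::ggplot(object$measurements,
                  ggplot2::aes(factor(.data$wavelength_nm),
                               .data$recovered_nm)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_point(data = object$recovered,
                        ggplot2::aes(y = .data$mean_recovered_nm),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "reference dye peak (nm)",
                  y = "recovered wavelength (nm)") +
    ggplot2::theme_minimal()
}
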