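#' Plot a set of spectra
#'
#' Overlays all spectra (absorbance against wavelength), one line per sample.
#'
#' @param x spectra table.
#' @param alpha line transparency.
#' @return a ggplot object.
#' @export
plot_spectra <- function(x, alpha = 0.4) {
  check_spectra(x)
  long <- tidyr::pivot_longer(x, -"sample_id", names_to = "wavelength",
                              values_to = "absorbance",
                              names_transform = as.numeric)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$absorbance,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance") +
    ggplot2::theme_minimal()
}

#' @method autoplot nir_cv
#' @export
autoplot.nir_cv <- function(object, ...) {
  m <- object$metrics
  ggplot2::ggplot(m, ggplot2::aes(.data$ncomp, .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = m[object$optimal_ncomp, ], colour = "red", size = 3) +
    ggplot2::labs(x = "PLS components", y = "RMSECV") +
    ggplot2::theme_minimal()
}

#' @method autoplot uve_result
#' @export
autoplot.uve_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$channel, .data$stability,
                                  colour = .data$block)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$p + 0.5, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "channel (real | noise)", y = "stability h") +
    ggplot2::theme_minimal()
}

#' @method autoplot cars_result
#' @export
autoplot.cars_result <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h[c("run", "n_channels", "rmsecv")], -"run")
  ggplot2::ggplot(long, ggplot2::aes(.data$run, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_run, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "sampling run", y = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-measured scatter plot
#'
#' @param predicted,measured numeric vectors.
#' @param label plot title (e.g. analyte and model).
#' @return a ggplot object with the 1:1 reference line.
#' @export
plot_predictions <- function(predicted, measured, label = NULL) {
  d <- tibble::tibble(measured = measured, predicted = predicted)
  ggplot2::ggplot(d, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(title = label, x = "reference (g/kg)", y = "predicted (g/kg)") +
    ggplot2::theme_minimal()
}
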