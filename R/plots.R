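#' Plot methods
#'
#' ggplot2 `autoplot()` methods for spectra, EEMs, titrations and fit
#' objects. Each returns a ggplot that can be further customized.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name specbind-plots
NULL

#' @rdname specbind-plots
#' @export
autoplot.spectrum <- function(object, ...) {
  ylab <- switch(spc_kind(object),
                 absorbance = "Absorbance (AU)",
                 fluorescence = "Fluorescence (a.u.)",
                 cd = "Ellipticity (mdeg)")
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.eem <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$emission, .data$excitation,
                               fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Intensity") +
    ggplot2::labs(x = "Emission (nm)", y = "Excitation (nm)") +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.titration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$conc * 1e6, .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "[Q] (µM)", y = "Fluorescence (a.u.)",
                  title = sprintf("T = %g K", titr_temperature(object))) +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.sv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc * 1e6, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$ksv * 1e-6, linetype = 2) +
    ggplot2::labs(x = "[Q] (µM)", y = expression(F[0] / F),
                  title = sprintf("Stern-Volmer, T = %g K: Ksv = %.3g M^-1",
                                  object$temperature, object$ksv)) +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.msv_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$inv_conc, .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 1 / object$fa,
                         slope = 1 / (object$fa * object$ka), linetype = 2) +
    ggplot2::labs(x = expression(1 / "[Q]" ~ (M^-1)),
                  y = expression(F[0] / (F[0] - F)),
                  title = sprintf("Modified Stern-Volmer: Ka = %.3g M^-1, fa = %.3g",
                                  object$ka, object$fa)) +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.hill_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$log_conc, .data$log_ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = log10(object$kb), slope = object$n,
                         linetype = 2) +
    ggplot2::labs(x = expression(log[10] * "[Q]"),
                  y = expression(log[10] * ((F[0] - F) / F)),
                  title = sprintf("Double-log fit: Kb = %.3g M^-1, n = %.2f",
                                  object$kb, object$n)) +
    ggplot2::theme_minimal()
}

#' @rdname specbind-plots
#' @export
autoplot.vant_hoff <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$inv_t, .data$log_k)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$delta_s / .R_GAS,
                         slope = -object$delta_h / .R_GAS, linetype = 2) +
    ggplot2::labs(x = expression(1 / T ~ (K^-1)), y = expression(ln ~ K),
                  title = sprintf("van't Hoff: dH = %.1f kJ/mol, dS = %.1f J/(mol K)",
                                  object$delta_h / 1000, object$delta_s)) +
    ggplot2::theme_minimal()
}
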