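#' Broom-style tidiers for specbind fit objects
#'
#' `tidy()` returns one row per fitted parameter on the natural scale;
#' `glance()` returns a one-row model summary suitable for row-binding
#' across temperatures or windows.
#'
#' @param x A fit object (`sv_fit`, `msv_fit`, `hill_fit`, `vant_hoff`,
#'   `fret_result`, `cd_result`).
#' @param ... Unused.
#' @return A tibble.
#' @name specbind-tidiers
NULL

se_or_na <- function(model, term) {
  if (is.null(model)) return(NA_real_)
  co <- suppressWarnings(summary(model))$coefficients
  if (term %in% rownames(co)) co[term, "Std. Error"] else NA_real_
}

#' @rdname specbind-tidiers
#' @export
tidy.sv_fit <- function(x, ...) {
  se <- se_or_na(x$model, "conc")
  tibble::tibble(
    term = c("ksv", "kq", "intercept"),
    estimate = c(x$ksv, x$kq, x$intercept),
    std.error = c(se, se / x$tau0, se_or_na(x$model, "(Intercept)")),
    unit = c("M^-1", "M^-1 s^-1", ""))
}

#' @rdname specbind-tidiers
#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(temperature = x$temperature, ksv = x$ksv, kq = x$kq,
                 intercept = x$intercept, r_squared = x$r_squared,
                 n_points = x$n_points, degenerate = x$degenerate)
}

#' @rdname specbind-tidiers
#' @export
tidy.msv_fit <- function(x, ...) {
  tibble::tibble(term = c("ka", "fa"), estimate = c(x$ka, x$fa),
                 unit = c("M^-1", ""))
}

#' @rdname specbind-tidiers
#' @export
glance.msv_fit <- function(x, ...) {
  tibble::tibble(temperature = x$temperature,
                 window_lo = x$window[1], window_hi = x$window[2],
                 ka = x$ka, fa = x$fa, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' @rdname specbind-tidiers
#' @export
tidy.hill_fit <- function(x, ...) {
  se_int <- se_or_na(x$model, "(Intercept)")
  tibble::tibble(
    term = c("kb", "n"),
    estimate = c(x$kb, x$n),
    # delta method on Kb = 10^intercept
    std.error = c(x$kb * log(10) * se_int, se_or_na(x$model, "log_conc")),
    unit = c("M^-1", ""))
}

#' @rdname specbind-tidiers
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(temperature = x$temperature, kb = x$kb, n = x$n,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' @rdname specbind-tidiers
#' @export
tidy.vant_hoff <- function(x, ...) {
  se_slope <- se_or_na(x$model, "inv_t")
  se_int <- se_or_na(x$model, "(Intercept)")
  tibble::tibble(
    term = c("delta_h", "delta_s"),
    estimate = c(x$delta_h, x$delta_s),
    std.error = c(.R_GAS * se_slope, .R_GAS * se_int),
    unit = c("J/mol", "J/(mol K)"))
}

#' @rdname specbind-tidiers
#' @export
glance.vant_hoff <- function(x, ...) {
  tibble::tibble(delta_h = x$delta_h, delta_s = x$delta_s,
                 r_squared = x$r_squared,
                 n_temperatures = length(x$temperatures),
                 force_class = classify_forces(x$delta_h, x$delta_s))
}

#' @rdname specbind-tidiers
#' @export
tidy.fret_result <- function(x, ...) {
  tibble::tibble(
    term = c("e", "j", "r0", "r"),
    estimate = c(x$e, x$j, x$r0, x$r),
    unit = c("", "M^-1 cm^-1 nm^4", "nm", "nm"))
}

#' @rdname specbind-tidiers
#' @export
glance.fret_result <- function(x, ...) {
  tibble::tibble(e = x$e, j = x$j, r0_nm = x$r0, r_nm = x$r,
                 kappa_sq = x$kappa_sq, valid_range = x$valid_range,
                 proximity = x$proximity)
}

#' @rdname specbind-tidiers
#' @export
tidy.cd_result <- function(x, ...) {
  tibble::tibble(term = c("mre_208", "helix_percent"),
                 estimate = c(x$mre_208, x$helix_percent),
                 unit = c("deg cm^2 dmol^-1", "%"))
}

#' @rdname specbind-tidiers
#' @export
glance.cd_result <- function(x, ...) {
  tibble::tibble(mre_208 = x$mre_208, helix_percent = x$helix_percent,
                 clamped = x$clamped)
}
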