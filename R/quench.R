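#' Stern-Volmer fit of a quenching titration
#'
#' Ordinary least squares of `F0/F` against quencher concentration `[Q]`.
#' The slope is the Stern-Volmer constant Ksv (M^-1); the bimolecular
#' quenching rate constant is `kq = Ksv / tau0`. The intercept is reported
#' and should be close to 1 for well-behaved data.
#'
#' @param series A [titration_series()] with inner-filter corrected
#'   intensities.
#' @param tau0 Unquenched fluorophore lifetime in seconds. Default `1e-8` s,
#'   the customary value for biopolymers.
#' @return An object of class `sv_fit` with elements `ksv` (M^-1), `kq`
#'   (M^-1 s^-1), `tau0`, `intercept`, `r_squared`, `degenerate`,
#'   `temperature`, `n_points`, and the underlying `lm` fit (`model`).
#' @examples
#' q <- c(0, 1, 5, 10, 20, 40, 80) * 1e-6
#' s <- titration_series(q, 1000 / (1 + 6.373e4 * q), temperature = 290)
#' stern_volmer_fit(s)
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  f0 <- titr_f0(series)
  if (!isTRUE(f0 > 0)) {
    rlang::abort("F0 must be positive.", class = "specbind_data_error")
  }
  pts <- series[series$conc > 0, ]
  if (any(pts$intensity <= 0)) {
    rlang::abort("All intensities must be positive.",
                 class = "specbind_data_error")
  }
  if (nrow(pts) < 3L) {
    rlang::abort("Need at least 3 nonzero-concentration points.",
                 class = "specbind_precondition_error")
  }
  if (all(pts$intensity == f0)) {
    return(new_sv_fit(ksv = 0, tau0 = tau0, intercept = 1, r_squared = NA_real_,
                      degenerate = TRUE, temperature = titr_temperature(series),
                      n_points = nrow(pts), model = NULL,
                      data = tibble::tibble(conc = pts$conc,
                                            ratio = f0 / pts$intensity)))
  }
  d <- tibble::tibble(conc = pts$conc, ratio = f0 / pts$intensity)
  m <- stats::lm(ratio ~ conc, data = d)
  new_sv_fit(ksv = unname(coef(m)[2]), tau0 = tau0,
             intercept = unname(coef(m)[1]),
             r_squared = suppressWarnings(summary(m))$r.squared,
             degenerate = FALSE, temperature = titr_temperature(series),
             n_points = nrow(pts), model = m, data = d)
}

new_sv_fit <- function(ksv, tau0, intercept, r_squared, degenerate,
                       temperature, n_points, model, data) {
  structure(list(ksv = ksv, kq = ksv / tau0, tau0 = tau0,
                 intercept = intercept, r_squared = r_squared,
                 degenerate = degenerate, temperature = temperature,
                 n_points = n_points, model = model, data = data),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer fit (T = %g K, %d points)\n  Ksv = %.4g M^-1  kq = %.4g M^-1 s^-1  intercept = %.4g  r2 = %.4f%s\n",
    x$temperature, x$n_points, x$ksv, x$kq, x$intercept,
    if (is.na(x$r_squared)) NA else x$r_squared,
    if (x$degenerate) "  [degenerate: no quenching]" else ""))
  invisible(x)
}

#' Modified Stern-Volmer fit (accessible-fraction model)
#'
#' Ordinary least squares of `F0/(F0 - F)` against `1/[Q]`, optionally
#' restricted to a concentration window. The accessible fraction is
#' `fa = 1/intercept` and the effective quenching constant is
#' `Ka = intercept/slope` (M^-1). Points with `F = F0` carry no quenching
#' information and are dropped with a warning.
#'
#' @param series A [titration_series()].
#' @param window Optional length-2 numeric, concentration window in mol/L
#'   (inclusive). `NULL` uses every nonzero concentration.
#' @return An object of class `msv_fit` with elements `ka` (M^-1), `fa`,
#'   `r_squared`, `window`, `temperature`, `n_points`, `model`, `data`.
#' @export
modified_sv_fit <- function(series, window = NULL) {
  f0 <- titr_f0(series)
  pts <- series[series$conc > 0, ]
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    pts <- pts[pts$conc >= min(window) & pts$conc <= max(window), ]
  }
  eq <- pts$intensity >= f0
  if (any(eq)) {
    rlang::warn(sprintf("%d point(s) with F >= F0 dropped.", sum(eq)))
    pts <- pts[!eq, ]
  }
  if (nrow(pts) < 3L) {
    rlang::abort("Need at least 3 quenched points inside the window.",
                 class = "specbind_fit_error")
  }
  d <- tibble::tibble(inv_conc = 1 / pts$conc,
                      ratio = f0 / (f0 - pts$intensity))
  m <- stats::lm(ratio ~ inv_conc, data = d)
  int <- unname(coef(m)[1]); slope <- unname(coef(m)[2])
  structure(list(ka = int / slope, fa = 1 / int,
                 r_squared = suppressWarnings(summary(m))$r.squared,
                 window = if (is.null(window)) range(pts$conc) else sort(window),
                 temperature = titr_temperature(series),
                 n_points = nrow(d), model = m, data = d),
            class = "msv_fit")
}

#' @export
print.msv_fit <- function(x, ...) {
  cat(sprintf(
    "Modified Stern-Volmer fit (T = %g K, window %.3g-%.3g M, %d points)\n  Ka = %.4g M^-1  fa = %.4g  r2 = %.4f\n",
    x$temperature, x$window[1], x$window[2], x$n_points,
    x$ka, x$fa, x$r_squared))
  invisible(x)
}

#' Detect biphasic quenching behavior
#'
#' Fits a quadratic to the modified Stern-Volmer transform
#' `F0/(F0 - F)` vs `1/[Q]`. A significantly negative quadratic coefficient
#' (concave-down curvature, t-statistic below `-t_threshold`) indicates two
#' quencher site classes being occupied at different concentration regimes;
#' default low/high analysis windows of 1-25 and 15-80 uM are then
#' returned. Single-site data are exactly linear in `1/[Q]` and yield one
#' full-range window.
#'
#' @param series A [titration_series()].
#' @param t_threshold Positive t-statistic threshold for the quadratic
#'   term. Default 2.
#' @param low_window,high_window Default windows (mol/L) reported when
#'   curvature is detected.
#' @return A list with `is_biphasic`, `curvature` (quadratic coefficient),
#'   `t_statistic`, and a named list `windows`.
#' @export
detect_biphasic <- function(series, t_threshold = 2,
                            low_window = c(1e-6, 25e-6),
                            high_window = c(15e-6, 80e-6)) {
  f0 <- titr_f0(series)
  pts <- series[series$conc > 0 & series$intensity < f0, ]
  full <- list(full = range(pts$conc))
  if (nrow(pts) < 6L) {
    return(list(is_biphasic = FALSE, curvature = NA_real_,
                t_statistic = NA_real_, windows = full,
                too_few_points = TRUE))
  }
  d <- tibble::tibble(x = 1 / pts$conc, y = f0 / (f0 - pts$intensity))
  m <- stats::lm(y ~ x + I(x^2), data = d)
  co <- suppressWarnings(summary(m))$coefficients
  curv <- co["I(x^2)", "Estimate"]
  tstat <- co["I(x^2)", "t value"]
  # practical significance: the quadratic term must bend the transform by a
  # non-negligible fraction of its range, or machine noise on exactly linear
  # data could trip the t-test
  bend <- abs(curv) * diff(range(d$x))^2 / 4
  material <- bend > 1e-6 * diff(range(d$y))
  biphasic <- is.finite(tstat) && curv < 0 && abs(tstat) > t_threshold &&
    material
  list(is_biphasic = biphasic, curvature = curv, t_statistic = tstat,
       windows = if (biphasic) list(low = low_window, high = high_window)
                 else full,
       too_few_points = FALSE)
}

#' Double-logarithmic (Hill) binding fit
#'
#' Ordinary least squares of `log10((F0 - F)/F)` against `log10([Q])`.
#' The slope is the number of binding sites `n` and the intercept is
#' `log10(Kb)`, giving the binding constant Kb in M^-1. Points with
#' `F >= F0` are dropped with a warning.
#'
#' @param series A [titration_series()].
#' @return An object of class `hill_fit` with elements `kb` (M^-1), `n`,
#'   `r_squared`, `temperature`, `n_points`, `model`, `data`.
#' @export
hill_fit <- function(series) {
  f0 <- titr_f0(series)
  pts <- series[series$conc > 0, ]
  bad <- pts$intensity >= f0
  if (any(bad)) {
    rlang::warn(sprintf("%d point(s) with F >= F0 dropped.", sum(bad)))
    pts <- pts[!bad, ]
  }
  if (nrow(pts) < 3L) {
    rlang::abort("Need at least 3 points with 0 < F < F0.",
                 class = "specbind_fit_error")
  }
  d <- tibble::tibble(log_conc = log10(pts$conc),
                      log_ratio = log10((f0 - pts$intensity) / pts$intensity))
  m <- stats::lm(log_ratio ~ log_conc, data = d)
  structure(list(kb = 10^unname(coef(m)[1]), n = unname(coef(m)[2]),
                 r_squared = suppressWarnings(summary(m))$r.squared,
                 temperature = titr_temperature(series),
                 n_points = nrow(d), model = m, data = d),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Double-log binding fit (T = %g K, %d points)\n  Kb = %.4g M^-1  n = %.3f  r2 = %.4f\n",
    x$temperature, x$n_points, x$kb, x$n, x$r_squared))
  invisible(x)
}

#' Classify the quenching mechanism across temperatures
#'
#' Static (ground-state complex) quenching weakens with temperature, so Ksv
#' decreases as T rises and the apparent kq exceeds the diffusion-limited
#' collisional maximum (~2e10 M^-1 s^-1). Dynamic (collisional) quenching
#' strengthens with temperature with kq at or below that limit. Upward
#' curvature of the Stern-Volmer plot signals both acting at once.
#'
#' @param sv_results A data frame with columns `temperature` (K), `ksv`
#'   (M^-1) and `kq` (M^-1 s^-1) — e.g. `tidy()` output of [stern_volmer_fit()]
#'   rows bound together — or a list of `sv_fit` objects.
#' @param curvature_flag `TRUE` when the Stern-Volmer plot deviates upward
#'   from linearity.
#' @param kq_limit Diffusion-limited collisional quenching constant,
#'   default `2e10` M^-1 s^-1.
#' @return One of `"static"`, `"dynamic"`, `"mixed"`, `"indeterminate"`.
#' @examples
#' classify_mechanism(tibble::tibble(
#'   temperature = c(290, 300, 310),
#'   ksv = c(6.373, 5.415, 4.566) * 1e4,
#'   kq = c(6.373, 5.415, 4.566) * 1e12))
#' @export
classify_mechanism <- function(sv_results, curvature_flag = FALSE,
                               kq_limit = 2e10) {
  if (is.list(sv_results) && !is.data.frame(sv_results) &&
      all(vapply(sv_results, inherits, logical(1), "sv_fit"))) {
    sv_results <- tibble::tibble(
      temperature = vapply(sv_results, `[[`, numeric(1), "temperature"),
      ksv = vapply(sv_results, `[[`, numeric(1), "ksv"),
      kq = vapply(sv_results, `[[`, numeric(1), "kq"))
  }
  if (isTRUE(curvature_flag)) return("mixed")
  d <- sv_results[order(sv_results$temperature), ]
  if (nrow(d) < 2L) {
    rlang::warn("Need >= 2 temperatures to classify a mechanism.")
    return("indeterminate")
  }
  decreasing <- all(diff(d$ksv) < 0)
  increasing <- all(diff(d$ksv) > 0)
  if (decreasing && all(d$kq > kq_limit)) return("static")
  if (increasing && all(d$kq <= kq_limit)) return("dynamic")
  "indeterminate"
}
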