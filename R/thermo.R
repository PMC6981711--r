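#' Van't Hoff fit of binding constants across temperatures
#'
#' Ordinary least squares of `ln K` against `1/T`:
#' `ln K = -dH/(R T) + dS/R`, so the enthalpy change is `-R * slope` and the
#' entropy change is `R * intercept`, with R = 8.314 J mol^-1 K^-1.
#'
#' @param k_by_t A data frame with columns `temperature` (K) and `k` (M^-1),
#'   at two or more distinct temperatures; all `k` positive.
#' @return An object of class `vant_hoff` with elements `delta_h` (J/mol),
#'   `delta_s` (J/(mol K)), `r_squared`, `model`, `data`. With exactly two
#'   temperatures the line is exact and `r_squared` is 1.
#' @examples
#' vant_hoff_fit(tibble::tibble(
#'   temperature = c(290, 300, 310),
#'   k = c(0.5506, 1.3590, 1.7459) * 1e4))
#' @export
vant_hoff_fit <- function(k_by_t) {
  stopifnot(all(c("temperature", "k") %in% names(k_by_t)))
  if (any(k_by_t$k <= 0)) {
    rlang::abort("All binding constants must be positive.",
                 class = "specbind_data_error")
  }
  if (length(unique(k_by_t$temperature)) < 2L) {
    rlang::abort("Need at least 2 distinct temperatures.",
                 class = "specbind_precondition_error")
  }
  d <- tibble::tibble(inv_t = 1 / k_by_t$temperature, log_k = log(k_by_t$k))
  m <- stats::lm(log_k ~ inv_t, data = d)
  r2 <- if (nrow(d) == 2L) 1 else suppressWarnings(summary(m))$r.squared
  structure(list(delta_h = -.R_GAS * unname(coef(m)[2]),
                 delta_s = .R_GAS * unname(coef(m)[1]),
                 r_squared = r2, model = m, data = d,
                 temperatures = sort(unique(k_by_t$temperature))),
            class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat(sprintf(
    "van't Hoff fit (%d temperatures)\n  dH = %.1f kJ/mol  dS = %.1f J/(mol K)  r2 = %.4f\n  force class: %s\n",
    length(x$temperatures), x$delta_h / 1000, x$delta_s, x$r_squared,
    classify_forces(x$delta_h, x$delta_s)))
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`.
#'
#' @param delta_h Enthalpy change, J/mol.
#' @param delta_s Entropy change, J/(mol K).
#' @param temperature Temperature(s) in K, positive.
#' @return Gibbs free energy change(s), J/mol.
#' @export
gibbs <- function(delta_h, delta_s, temperature) {
  if (any(temperature <= 0)) {
    rlang::abort("Temperature must be positive (K).",
                 class = "specbind_precondition_error")
  }
  delta_h - temperature * delta_s
}

#' Gibbs free energy from an equilibrium constant
#'
#' The alternative convention `dG = -R T ln K`, useful for temperature-wise
#' free energies when only the constant at that temperature is known.
#'
#' @param k Equilibrium (binding) constant, M^-1, positive.
#' @param temperature Temperature in K, positive.
#' @return Gibbs free energy change(s), J/mol.
#' @export
gibbs_from_k <- function(k, temperature) {
  if (any(k <= 0) || any(temperature <= 0)) {
    rlang::abort("`k` and `temperature` must be positive.",
                 class = "specbind_precondition_error")
  }
  -.R_GAS * temperature * log(k)
}

#' Classify the dominant interaction force from thermodynamic signs
#'
#' Sign-table heuristic: positive dH and dS indicate hydrophobic
#' interactions; both negative indicate hydrogen bonding / van der Waals
#' contacts; negative dH with positive dS indicates electrostatic
#' interactions; anything else (including zeros) is reported as mixed.
#'
#' @param delta_h Enthalpy change, J/mol.
#' @param delta_s Entropy change, J/(mol K).
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"mixed"`.
#' @export
classify_forces <- function(delta_h, delta_s) {
  dplyr::case_when(
    delta_h > 0 & delta_s > 0 ~ "hydrophobic",
    delta_h < 0 & delta_s < 0 ~ "hbond_vdw",
    delta_h < 0 & delta_s > 0 ~ "electrostatic",
    TRUE ~ "mixed")
}

#' Full thermodynamic characterization of a binding series
#'
#' Runs [vant_hoff_fit()], evaluates `dG = dH - T dS` at each input
#' temperature, and classifies the dominant force.
#'
#' @inheritParams vant_hoff_fit
#' @return An object of class `thermo_result`: the `vant_hoff` elements plus
#'   `delta_g_by_t` (tibble of `temperature`, `delta_g` J/mol) and
#'   `force_class`.
#' @export
binding_thermodynamics <- function(k_by_t) {
  vh <- vant_hoff_fit(k_by_t)
  tt <- sort(unique(k_by_t$temperature))
  out <- unclass(vh)
  out$delta_g_by_t <- tibble::tibble(
    temperature = tt,
    delta_g = gibbs(vh$delta_h, vh$delta_s, tt))
  out$force_class <- classify_forces(vh$delta_h, vh$delta_s)
  structure(out, class = c("thermo_result", "vant_hoff"))
}

#' @export
print.thermo_result <- function(x, ...) {
  NextMethod()
  dg <- sprintf("%.1f", x$delta_g_by_t$delta_g / 1000)
  cat(sprintf("  dG (kJ/mol) at %s K: %s\n",
              paste(x$delta_g_by_t$temperature, collapse = ", "),
              paste(dg, collapse = ", ")))
  invisible(x)
}
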