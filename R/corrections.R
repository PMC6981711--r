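#' Inner-filter correction of fluorescence intensities
#'
#' Measured fluorescence in a right-angle cuvette is attenuated by absorption
#' of the excitation beam on the way in and of the emitted light on the way
#' out. The standard correction multiplies the observed intensity by
#' `10^((Aex + Aem)/2)` where `Aex` and `Aem` are the solution absorbances at
#' the excitation and emission wavelengths. A natural-exponent variant
#' (`exp((Aex + Aem)/2)`) is selectable but is not the default.
#'
#' @param f_obs Observed fluorescence intensities (a.u.), nonnegative.
#' @param a_ex Absorbance at the excitation wavelength (AU), nonnegative.
#' @param a_em Absorbance at the emission wavelength (AU), nonnegative.
#' @param convention `"log10_sum"` (default) or `"exp_sum"`.
#' @return Corrected fluorescence intensities, `>= f_obs`.
#' @examples
#' inner_filter_correct(100, 0.1, 0.05)  # 118.85
#' @export
inner_filter_correct <- function(f_obs, a_ex, a_em,
                                 convention = c("log10_sum", "exp_sum")) {
  convention <- rlang::arg_match(convention)
  if (any(!is.finite(a_ex)) || any(!is.finite(a_em)) ||
      any(a_ex < 0) || any(a_em < 0)) {
    rlang::abort("Absorbances must be finite and nonnegative.",
                 class = "specbind_precondition_error")
  }
  if (any(f_obs < 0)) {
    rlang::abort("Observed fluorescence must be nonnegative.",
                 class = "specbind_precondition_error")
  }
  s <- (a_ex + a_em) / 2
  if (convention == "log10_sum") f_obs * 10^s else f_obs * exp(s)
}

#' Apply inner-filter correction to a titration series
#'
#' Convenience wrapper correcting every intensity of a [titration_series()]
#' with per-point absorbances (e.g. from the quencher's absorption spectrum
#' at the excitation and emission wavelengths, proportional to its
#' concentration).
#'
#' @param series A [titration_series()].
#' @inheritParams inner_filter_correct
#' @return A corrected `titration` with the same attributes.
#' @export
correct_titration <- function(series, a_ex, a_em,
                              convention = c("log10_sum", "exp_sum")) {
  f <- inner_filter_correct(series$intensity, a_ex, a_em, convention)
  titration_series(series$conc, f,
                   temperature = titr_temperature(series),
                   em_wavelength = attr(series, "em_wavelength"),
                   ex_wavelength = attr(series, "ex_wavelength"))
}
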