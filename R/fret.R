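#' FRET transfer efficiency from donor intensities
#'
#' `E = (F0 - F)/F0`, the fraction of donor excitation lost to the acceptor,
#' measured from donor fluorescence with (`f`) and without (`f0`) acceptor
#' at matched donor/acceptor concentrations.
#'
#' @param f0 Donor intensity without acceptor, positive.
#' @param f Donor intensity with acceptor, `0 <= f <= f0`.
#' @return Efficiency in `[0, 1]`.
#' @export
transfer_efficiency <- function(f0, f) {
  if (any(f0 <= 0)) {
    rlang::abort("F0 must be positive.", class = "specbind_data_error")
  }
  if (any(f < 0) || any(f > f0)) {
    rlang::abort("F must satisfy 0 <= F <= F0.",
                 class = "specbind_data_error")
  }
  (f0 - f) / f0
}

#' Spectral overlap integral of donor emission and acceptor absorption
#'
#' `J = integral(F(l) eps(l) l^4 dl) / integral(F(l) dl)` with wavelength in
#' nm and the acceptor's molar extinction coefficient in M^-1 cm^-1, giving
#' J in M^-1 cm^-1 nm^4. Both spectra are resampled onto a common uniform
#' grid over their overlap and integrated by the trapezoidal rule.
#' Non-overlapping spectra return 0 with a warning.
#'
#' @param donor_emission Fluorescence [spectrum()] of the donor (any
#'   intensity scale; J is scale-invariant in F).
#' @param acceptor_absorption [spectrum()] of the acceptor's molar
#'   extinction coefficient, M^-1 cm^-1 (stored as kind "absorbance").
#' @param grid_step Common grid step in nm. Default 0.5.
#' @return Overlap integral J, M^-1 cm^-1 nm^4.
#' @export
overlap_integral <- function(donor_emission, acceptor_absorption,
                             grid_step = 0.5) {
  lo <- max(min(donor_emission$wavelength), min(acceptor_absorption$wavelength))
  hi <- min(max(donor_emission$wavelength), max(acceptor_absorption$wavelength))
  if (lo >= hi) {
    rlang::warn("Donor emission and acceptor absorption do not overlap; J = 0.")
    return(0)
  }
  grid <- seq(lo, hi, by = grid_step)
  if (length(grid) < 2L) grid <- c(lo, hi)
  f <- resample(donor_emission, grid)$value
  eps <- resample(acceptor_absorption, grid)$value
  denom <- pracma::trapz(grid, f)
  if (denom <= 0) {
    rlang::warn("Donor emission integrates to zero over the overlap; J = 0.")
    return(0)
  }
  pracma::trapz(grid, f * eps * grid^4) / denom
}

#' Forster radius from the overlap integral
#'
#' `R0 = 0.211 * (kappa^2 n^-4 phi_D J)^(1/6)` in Angstrom when J is in
#' M^-1 cm^-1 nm^4; the result is returned in nm. R0 is the donor-acceptor
#' separation at which transfer and spontaneous emission are equally likely.
#'
#' @param j Overlap integral, M^-1 cm^-1 nm^4, nonnegative.
#' @param kappa_sq Dipole orientation factor in `[0, 4]`. 2/3 for freely
#'   tumbling dyes; 0.476 for static random orientations.
#' @param refractive_index Medium refractive index, `>= 1`. Default 1.336.
#' @param quantum_yield Donor fluorescence quantum yield in `(0, 1]`.
#'   Default 0.15.
#' @return Forster radius R0 in nm.
#' @export
forster_radius <- function(j, kappa_sq = 2 / 3, refractive_index = 1.336,
                           quantum_yield = 0.15) {
  if (any(j < 0)) {
    rlang::abort("J must be nonnegative.", class = "specbind_precondition_error")
  }
  stopifnot(kappa_sq >= 0, kappa_sq <= 4,
            quantum_yield > 0, quantum_yield <= 1, refractive_index >= 1)
  r0_angstrom <- 0.211 *
    (kappa_sq * quantum_yield * j / refractive_index^4)^(1 / 6)
  r0_angstrom / 10
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inverts `E = R0^6 / (R0^6 + r^6)` to `r = R0 ((1 - E)/E)^(1/6)` and
#' attaches the two customary validity checks: `0.5 R0 < r < 1.5 R0`
#' (distance resolvable from E) and `2 <= r <= 8` nm (FRET proximity
#' window).
#'
#' @param efficiency Transfer efficiency in `(0, 1)`; `E = 1` returns
#'   `r = 0`, `E = 0` returns `Inf` with a warning.
#' @param r0 Forster radius in nm, positive.
#' @return A list with `r` (nm), `valid_range`, `proximity`.
#' @examples
#' donor_acceptor_distance(0.19, 2.72)$r  # 3.46 nm
#' @export
donor_acceptor_distance <- function(efficiency, r0) {
  stopifnot(r0 > 0, efficiency >= 0, efficiency <= 1)
  if (efficiency == 0) {
    rlang::warn("E = 0: no measurable transfer, distance unbounded.")
    r <- Inf
  } else if (efficiency == 1) {
    r <- 0
  } else {
    r <- r0 * ((1 - efficiency) / efficiency)^(1 / 6)
  }
  list(r = r,
       valid_range = is.finite(r) && r > 0.5 * r0 && r < 1.5 * r0,
       proximity = is.finite(r) && r >= 2 && r <= 8)
}

#' Complete FRET analysis
#'
#' Chains [transfer_efficiency()], [overlap_integral()], [forster_radius()]
#' and [donor_acceptor_distance()] into one result object.
#'
#' @inheritParams overlap_integral
#' @inheritParams forster_radius
#' @param f0,f Donor intensities without / with acceptor.
#' @return An object of class `fret_result` with elements `e`, `j`, `r0`
#'   (nm), `r` (nm), `valid_range`, `proximity`, and the parameters used.
#' @export
fret_analysis <- function(donor_emission, acceptor_absorption, f0, f,
                          kappa_sq = 2 / 3, refractive_index = 1.336,
                          quantum_yield = 0.15, grid_step = 0.5) {
  e <- transfer_efficiency(f0, f)
  j <- overlap_integral(donor_emission, acceptor_absorption, grid_step)
  r0 <- forster_radius(j, kappa_sq, refractive_index, quantum_yield)
  dist <- if (r0 > 0 && e > 0 && e < 1) {
    donor_acceptor_distance(e, r0)
  } else {
    list(r = NA_real_, valid_range = FALSE, proximity = FALSE)
  }
  structure(list(e = e, j = j, r0 = r0, r = dist$r,
                 valid_range = dist$valid_range, proximity = dist$proximity,
                 kappa_sq = kappa_sq, refractive_index = refractive_index,
                 quantum_yield = quantum_yield),
            class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf(
    "FRET analysis (kappa^2 = %.3f, n = %.3f, phi_D = %.2f)\n  E = %.3f  J = %.3g M^-1 cm^-1 nm^4  R0 = %.2f nm  r = %.2f nm\n  0.5 R0 < r < 1.5 R0: %s   2 <= r <= 8 nm: %s\n",
    x$kappa_sq, x$refractive_index, x$quantum_yield,
    x$e, x$j, x$r0, x$r, x$valid_range, x$proximity))
  invisible(x)
}
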