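#' Construct a spectrum
#'
#' A spectrum is a tibble with columns `wavelength` (nm, strictly increasing)
#' and `value` (absorbance AU, fluorescence a.u., or CD millidegrees),
#' carrying its `kind` and free-form acquisition metadata as attributes.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of intensities, same length as `wavelength`.
#' @param kind One of `"absorbance"`, `"fluorescence"`, `"cd"`.
#' @param meta Named list of acquisition metadata (e.g. `temperature` in K,
#'   `excitation` in nm, `path_cm`, `label`).
#'
#' @return A tibble of class `spectrum` with columns `wavelength`, `value`.
#' @examples
#' s <- spectrum(200:400, dnorm(200:400, 340, 20), kind = "fluorescence")
#' spc_kind(s)
#' @export
spectrum <- function(wavelength, value,
                     kind = c("absorbance", "fluorescence", "cd"),
                     meta = list()) {
  kind <- rlang::arg_match(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    rlang::abort("`wavelength` and `value` must have the same length.",
                 class = "specbind_length_error")
  }
  if (length(wavelength) == 0L) {
    rlang::abort("A spectrum needs at least one point.",
                 class = "specbind_length_error")
  }
  if (any(diff(wavelength) <= 0)) {
    rlang::abort("`wavelength` must be strictly increasing.",
                 class = "specbind_grid_error")
  }
  out <- tibble::tibble(wavelength = wavelength, value = value)
  attr(out, "kind") <- kind
  attr(out, "meta") <- meta
  class(out) <- c("spectrum", class(out))
  out
}

#' @rdname spectrum
#' @param x A data frame with columns `wavelength` and `value`, or a
#'   `spectrum`.
#' @export
as_spectrum <- function(x, kind = c("absorbance", "fluorescence", "cd"),
                        meta = list()) {
  if (inherits(x, "spectrum")) return(x)
  stopifnot(all(c("wavelength", "value") %in% names(x)))
  spectrum(x$wavelength, x$value, kind = kind, meta = meta)
}

#' @rdname spectrum
#' @export
spc_kind <- function(x) attr(x, "kind")

#' @rdname spectrum
#' @export
spc_meta <- function(x) attr(x, "meta") %||% list()

# rebuild a spectrum from a template, preserving kind/meta
spc_update <- function(template, wavelength, value, meta = spc_meta(template)) {
  spectrum(wavelength, value, kind = spc_kind(template), meta = meta)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.1f-%.1f nm>\n",
              spc_kind(x), nrow(x), min(x$wavelength), max(x$wavelength)))
  NextMethod()
}

is_uniform_grid <- function(wavelength, tol = 1e-8) {
  if (length(wavelength) < 3L) return(TRUE)
  d <- diff(wavelength)
  max(d) - min(d) <= tol * max(abs(d))
}

grid_step <- function(x) {
  d <- diff(x$wavelength)
  if (length(d) == 0L) return(NA_real_)
  stats::median(d)
}

#' Construct an excitation-emission matrix (EEM)
#'
#' Stores a fluorescence landscape as a long tibble with one row per
#' (excitation, emission) grid point. The dense matrix view is available via
#' [eem_matrix()].
#'
#' @param excitation Increasing numeric vector, excitation axis in nm.
#' @param emission Increasing numeric vector, emission axis in nm.
#' @param intensities Matrix of intensities, `length(excitation)` rows by
#'   `length(emission)` columns.
#'
#' @return A tibble of class `eem` with columns `excitation`, `emission`,
#'   `intensity`.
#' @export
eem <- function(excitation, emission, intensities) {
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  intensities <- as.matrix(intensities)
  if (any(diff(excitation) <= 0) || any(diff(emission) <= 0)) {
    rlang::abort("EEM axes must be strictly increasing.",
                 class = "specbind_grid_error")
  }
  if (!identical(dim(intensities),
                 c(length(excitation), length(emission)))) {
    rlang::abort("`intensities` must be excitation x emission.",
                 class = "specbind_length_error")
  }
  out <- tidyr::expand_grid(excitation = excitation, emission = emission)
  out$intensity <- as.vector(t(intensities))
  attr(out, "ex_axis") <- excitation
  attr(out, "em_axis") <- emission
  class(out) <- c("eem", class(out))
  out
}

#' @rdname eem
#' @param x An `eem`.
#' @return For `eem_matrix()`, the intensity matrix (excitation rows,
#'   emission columns) with axes as dimnames.
#' @export
eem_matrix <- function(x) {
  ex <- attr(x, "ex_axis")
  em <- attr(x, "em_axis")
  m <- matrix(x$intensity, nrow = length(ex), ncol = length(em), byrow = TRUE)
  dimnames(m) <- list(excitation = ex, emission = em)
  m
}

#' @export
print.eem <- function(x, ...) {
  ex <- attr(x, "ex_axis"); em <- attr(x, "em_axis")
  cat(sprintf("<eem: %d x %d (ex %.0f-%.0f nm, em %.0f-%.0f nm)>\n",
              length(ex), length(em), min(ex), max(ex), min(em), max(em)))
  NextMethod()
}

#' Construct a fluorescence titration series
#'
#' A titration series records (inner-filter corrected) fluorescence intensity
#' at one fixed emission wavelength as a function of quencher concentration,
#' at one temperature. The first concentration must be exactly zero; its
#' intensity defines F0.
#'
#' @param conc Quencher concentrations in mol/L, nondecreasing, first entry 0.
#' @param intensity Fluorescence intensities (a.u.), all positive.
#' @param temperature Temperature in K.
#' @param em_wavelength Emission wavelength in nm (default 340).
#' @param ex_wavelength Excitation wavelength in nm (default 280).
#'
#' @return A tibble of class `titration` with columns `conc`, `intensity`.
#' @examples
#' q <- c(0, 1, 5, 10, 20, 40, 80) * 1e-6
#' titration_series(q, 1000 / (1 + 5e4 * q), temperature = 298)
#' @export
titration_series <- function(conc, intensity, temperature,
                             em_wavelength = 340, ex_wavelength = 280) {
  conc <- as.numeric(conc)
  intensity <- as.numeric(intensity)
  if (length(conc) != length(intensity)) {
    rlang::abort("`conc` and `intensity` must have the same length.",
                 class = "specbind_length_error")
  }
  if (length(conc) == 0L || conc[1] != 0) {
    rlang::abort("The first concentration must be exactly 0 (defines F0).",
                 class = "specbind_data_error")
  }
  if (any(diff(conc) < 0)) {
    rlang::abort("Concentrations must be nondecreasing.",
                 class = "specbind_data_error")
  }
  if (any(intensity <= 0)) {
    rlang::abort("All intensities must be positive.",
                 class = "specbind_data_error")
  }
  out <- tibble::tibble(conc = conc, intensity = intensity)
  attr(out, "temperature") <- as.numeric(temperature)
  attr(out, "em_wavelength") <- em_wavelength
  attr(out, "ex_wavelength") <- ex_wavelength
  class(out) <- c("titration", class(out))
  out
}

#' @rdname titration_series
#' @param x A `titration`.
#' @export
titr_temperature <- function(x) attr(x, "temperature")

#' @rdname titration_series
#' @export
titr_f0 <- function(x) x$intensity[x$conc == 0][1]

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("<titration: %d points, T = %g K, F0 = %.4g>\n",
              nrow(x), titr_temperature(x), titr_f0(x)))
  NextMethod()
}
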