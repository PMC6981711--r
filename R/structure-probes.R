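#' Synchronous fluorescence spectrum from an EEM
#'
#' Extracts the trace along the diagonal `emission = excitation + delta_lambda`
#' by bilinear interpolation on the EEM grid, indexed by excitation
#' wavelength. Offsets of 15 and 60 nm probe the tyrosine and tryptophan
#' microenvironments respectively.
#'
#' @param x An [eem()].
#' @param delta_lambda Constant excitation-emission offset in nm, positive.
#' @return A fluorescence [spectrum()] indexed by excitation wavelength, with
#'   `meta$delta_lambda` set.
#' @export
synchronous_spectrum <- function(x, delta_lambda) {
  stopifnot(delta_lambda > 0)
  ex <- attr(x, "ex_axis")
  em <- attr(x, "em_axis")
  keep <- ex + delta_lambda >= min(em) & ex + delta_lambda <= max(em)
  if (!any(keep)) {
    rlang::abort(
      sprintf("Diagonal em = ex + %g nm does not intersect the EEM domain.",
              delta_lambda),
      class = "specbind_range_error")
  }
  exs <- ex[keep]
  m <- eem_matrix(x)
  vals <- vapply(exs, function(e) {
    tgt <- e + delta_lambda
    j <- findInterval(tgt, em, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(em) - 1L)
    w <- (tgt - em[j]) / (em[j + 1] - em[j])
    i <- match(e, ex)
    (1 - w) * m[i, j] + w * m[i, j + 1]
  }, numeric(1))
  spectrum(exs, vals, kind = "fluorescence",
           meta = list(delta_lambda = delta_lambda, axis = "excitation"))
}

#' Classify a spectral peak shift
#'
#' Compares the dominant peak position of a perturbed spectrum with a
#' reference. A shift to longer wavelength (red) indicates increased polarity
#' of the fluorophore microenvironment; a shift to shorter wavelength (blue)
#' indicates increased hydrophobicity. Shifts within `tolerance` are
#' reported as none.
#'
#' @param reference,perturbed Spectra, unimodal in the analysis window.
#' @param tolerance Shift magnitude (nm) treated as no shift. Default 1.
#' @param min_prominence Passed to [find_peaks()].
#' @return A list with `delta` (nm, perturbed minus reference) and `label`
#'   (`"red"`, `"blue"`, or `"none"`).
#' @export
classify_shift <- function(reference, perturbed, tolerance = 1,
                           min_prominence = 0.01) {
  p_ref <- peak_wavelength(reference, min_prominence)
  p_per <- peak_wavelength(perturbed, min_prominence)
  delta <- p_per - p_ref
  label <- if (abs(delta) <= tolerance) "none" else if (delta > 0) "red" else "blue"
  list(delta = delta, label = label)
}

#' Mean residue ellipticity
#'
#' Normalizes an observed CD signal (millidegrees) by protein concentration,
#' residue count and path length:
#' `MRE = theta_obs / (10 Cp n l)` in deg cm^2 dmol^-1, with `Cp` in mol/L,
#' `l` in cm.
#'
#' @param theta_obs Observed ellipticity, millidegrees.
#' @param cp Molar protein concentration, mol/L, positive.
#' @param n_residues Number of amino-acid residues, positive.
#' @param path_cm Cuvette path length in cm, positive.
#' @return Mean residue ellipticity, deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(theta_obs, cp, n_residues, path_cm) {
  if (any(cp <= 0) || any(n_residues <= 0) || any(path_cm <= 0)) {
    rlang::abort("`cp`, `n_residues` and `path_cm` must be positive.",
                 class = "specbind_precondition_error")
  }
  theta_obs / (10 * cp * n_residues * path_cm)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' `helix% = 100 (-MRE208 - 4000) / (33000 - 4000)`, anchored at the
#' canonical MRE of pure alpha-helix (-33000) and of beta/random-coil
#' (-4000) at 208 nm. Raw values outside 0-100 are reported unclamped with
#' the `clamped` flag set.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm, deg cm^2 dmol^-1.
#' @return An object of class `cd_result`: `mre_208`, `helix_percent`
#'   (raw), `clamped`.
#' @examples
#' helix_fraction(-25129.4)$helix_percent  # 72.86
#' @export
helix_fraction <- function(mre_208) {
  pct <- 100 * (-mre_208 - 4000) / (33000 - 4000)
  structure(list(mre_208 = mre_208, helix_percent = pct,
                 clamped = pct < 0 | pct > 100),
            class = "cd_result")
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf("CD result: MRE208 = %.0f deg cm^2 dmol^-1 -> alpha-helix %.2f%%%s\n",
              x$mre_208, x$helix_percent,
              if (any(x$clamped)) " [outside 0-100, reported raw]" else ""))
  invisible(x)
}

#' Alpha-helix content directly from a CD spectrum
#'
#' Reads the ellipticity at 208 nm off the grid (nearest point within half a
#' grid step), converts to mean residue ellipticity and applies
#' [helix_fraction()].
#'
#' @param x A CD [spectrum()] in millidegrees.
#' @inheritParams mean_residue_ellipticity
#' @param wavelength Evaluation wavelength in nm. Default 208.
#' @return A `cd_result`.
#' @export
helix_from_cd <- function(x, cp, n_residues, path_cm, wavelength = 208) {
  if (!identical(spc_kind(x), "cd")) {
    rlang::abort("`x` must be a CD spectrum.", class = "specbind_type_error")
  }
  i <- which.min(abs(x$wavelength - wavelength))
  if (abs(x$wavelength[i] - wavelength) > grid_step(x) / 2 + 1e-9) {
    rlang::abort(sprintf("No grid point near %g nm.", wavelength),
                 class = "specbind_range_error")
  }
  mre <- mean_residue_ellipticity(x$value[i], cp, n_residues, path_cm)
  helix_fraction(mre)
}
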