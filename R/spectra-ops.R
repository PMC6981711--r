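#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`; kind and metadata are preserved. The
#' grid must lie within the source wavelength range (no extrapolation).
#'
#' @param x A [spectrum()].
#' @param grid Numeric vector of target wavelengths in nm, strictly
#'   increasing, within the source range.
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(x, grid) {
  grid <- as.numeric(grid)
  if (min(grid) < min(x$wavelength) || max(grid) > max(x$wavelength)) {
    rlang::abort(
      sprintf("Target grid [%g, %g] nm outside source range [%g, %g] nm.",
              min(grid), max(grid), min(x$wavelength), max(x$wavelength)),
      class = "specbind_range_error")
  }
  v <- stats::approx(x$wavelength, x$value, xout = grid, method = "linear")$y
  spc_update(x, grid, v)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' Returns the smoothed second derivative d2(value)/d(wavelength)2 computed
#' with a Savitzky-Golay polynomial filter. The spectrum must be on a uniform
#' grid (use [resample()] first otherwise). Edge points are computed with the
#' filter's truncated-window (one-sided) convention and the result is flagged
#' in its metadata.
#'
#' @param x A [spectrum()] on a uniform wavelength grid.
#' @param window_points Odd filter window length (points). Default 21.
#' @param poly_order Polynomial order, less than `window_points`. Default 3.
#' @return A `spectrum` holding the second derivative (units value / nm^2),
#'   with `meta$derivative = 2` and `meta$edge_convention`.
#' @export
savgol_second_derivative <- function(x, window_points = 21, poly_order = 3) {
  if (window_points %% 2 != 1 || window_points <= poly_order) {
    rlang::abort("`window_points` must be odd and greater than `poly_order`.",
                 class = "specbind_precondition_error")
  }
  if (!is_uniform_grid(x$wavelength)) {
    rlang::abort("Spectrum must be on a uniform grid; resample() first.",
                 class = "specbind_precondition_error")
  }
  if (nrow(x) < window_points) {
    rlang::abort("Spectrum shorter than the filter window.",
                 class = "specbind_precondition_error")
  }
  h <- grid_step(x)
  d2 <- signal::sgolayfilt(x$value, p = poly_order, n = window_points,
                           m = 2, ts = h)
  meta <- spc_meta(x)
  meta$derivative <- 2
  meta$edge_convention <- "truncated_window"
  spc_update(x, x$wavelength, d2, meta = meta)
}

#' Subtract a blank spectrum
#'
#' Pointwise difference `sample - blank` on their common wavelength range,
#' evaluated on the sample's grid (the blank is linearly interpolated).
#' Both spectra must be of the same kind and must overlap.
#'
#' @param sample,blank Spectra of the same kind.
#' @return A `spectrum` on the overlapping part of the sample grid.
#' @export
subtract_blank <- function(sample, blank) {
  if (!identical(spc_kind(sample), spc_kind(blank))) {
    rlang::abort(
      sprintf("Kind mismatch: sample is %s, blank is %s.",
              spc_kind(sample), spc_kind(blank)),
      class = "specbind_type_error")
  }
  lo <- max(min(sample$wavelength), min(blank$wavelength))
  hi <- min(max(sample$wavelength), max(blank$wavelength))
  if (lo > hi) {
    rlang::abort("Spectra do not overlap in wavelength.",
                 class = "specbind_range_error")
  }
  keep <- sample$wavelength >= lo & sample$wavelength <= hi
  grid <- sample$wavelength[keep]
  b <- stats::approx(blank$wavelength, blank$value, xout = grid)$y
  spc_update(sample, grid, sample$value[keep] - b)
}

#' Locate peaks in a spectrum
#'
#' Finds local maxima (or minima, for derivative traces) with a prominence
#' filter. Prominence of a peak is the height above the higher of the two
#' bracketing minima on the walk to the nearest taller point (or trace end),
#' expressed as a fraction of the trace's maximum absolute value. Peaks
#' within one grid step of either boundary are discarded (edge artifacts).
#'
#' @param x A [spectrum()].
#' @param min_prominence Minimum prominence, as a fraction of
#'   `max(abs(value))`. Default 0.01.
#' @param direction `"max"` (default) for maxima, `"min"` for minima.
#' @return A tibble with columns `wavelength`, `value`, `prominence`,
#'   sorted by wavelength. May be empty.
#' @export
find_peaks <- function(x, min_prominence = 0.01,
                       direction = c("max", "min")) {
  direction <- rlang::arg_match(direction)
  v <- x$value
  if (direction == "min") v <- -v
  n <- length(v)
  empty <- tibble::tibble(wavelength = numeric(), value = numeric(),
                          prominence = numeric())
  if (n < 3L) return(empty)
  # strict local maxima; plateaus take their leftmost point
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  # drop peaks at (or within one step of) the boundary
  cand <- cand[cand > 2L & cand < n - 1L]
  if (length(cand) == 0L) return(empty)
  scale <- max(abs(v))
  if (scale == 0) return(empty)
  prom <- vapply(cand, function(i) {
    left <- v[seq_len(i - 1L)]
    right <- v[seq(i + 1L, n)]
    higher_l <- which(left > v[i])
    higher_r <- which(right > v[i])
    base_l <- if (length(higher_l)) min(v[seq(max(higher_l), i - 1L)]) else min(left)
    base_r <- if (length(higher_r)) min(v[i + seq_len(min(higher_r))]) else min(right)
    v[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- prom / scale >= min_prominence
  cand <- cand[keep]
  tibble::tibble(wavelength = x$wavelength[cand],
                 value = x$value[cand],
                 prominence = prom[keep] / scale)
}

#' @rdname find_peaks
#' @details `peak_wavelength()` returns the wavelength of the single most
#'   intense peak, erroring when none is found.
#' @export
peak_wavelength <- function(x, min_prominence = 0.01,
                            direction = c("max", "min")) {
  p <- find_peaks(x, min_prominence, direction)
  if (nrow(p) == 0L) {
    rlang::abort("No peak found in spectrum.", class = "specbind_analysis_error")
  }
  p$wavelength[which.max(abs(p$value))]
}
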