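#' Read and write spectra as delimited text
#'
#' Spectra are stored as two-column tab-delimited text
#' (`wavelength_nm`, `value`) preceded by comment lines of the form
#' `# key=value` carrying the kind and acquisition metadata.
#'
#' @param path File path.
#' @return `read_spectrum()` returns a [spectrum()].
#' @export
read_spectrum <- function(path) {
  hdr <- read_header(path)
  kind <- hdr$kind %||% "absorbance"
  hdr$kind <- NULL
  d <- readr::read_tsv(path, comment = "#", col_names = c("wavelength", "value"),
                       col_types = "dd", progress = FALSE)
  spectrum(d$wavelength, d$value, kind = kind, meta = hdr)
}

#' @rdname read_spectrum
#' @param x A [spectrum()].
#' @export
write_spectrum <- function(x, path) {
  meta <- c(list(kind = spc_kind(x)), spc_meta(x))
  write_header(meta, path)
  readr::write_tsv(tibble::tibble(wavelength_nm = x$wavelength,
                                  value = x$value),
                   path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read and write titration series as delimited text
#'
#' Tables with columns (`conc_M`, `intensity`), one file per temperature;
#' the temperature (K) and wavelengths live in `# key=value` header lines.
#'
#' @param path File path.
#' @return `read_titration()` returns a [titration_series()].
#' @export
read_titration <- function(path) {
  hdr <- read_header(path)
  d <- readr::read_tsv(path, comment = "#", col_names = c("conc", "intensity"),
                       col_types = "dd", progress = FALSE)
  titration_series(d$conc, d$intensity,
                   temperature = as.numeric(hdr$temperature),
                   em_wavelength = as.numeric(hdr$em_wavelength %||% 340),
                   ex_wavelength = as.numeric(hdr$ex_wavelength %||% 280))
}

#' @rdname read_titration
#' @param x A [titration_series()].
#' @export
write_titration <- function(x, path) {
  write_header(list(temperature = titr_temperature(x),
                    em_wavelength = attr(x, "em_wavelength"),
                    ex_wavelength = attr(x, "ex_wavelength")), path)
  readr::write_tsv(tibble::tibble(conc_M = x$conc, intensity = x$intensity),
                   path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read and write excitation-emission matrices as delimited grids
#'
#' First row holds the emission axis (first cell blank), first column the
#' excitation axis, the body the intensities.
#'
#' @param path File path.
#' @return `read_eem()` returns an [eem()].
#' @export
read_eem <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  em <- as.numeric(m[1, -1])
  ex <- as.numeric(m[-1, 1])
  eem(ex, em, matrix(as.numeric(m[-1, -1]), nrow = length(ex)))
}

#' @rdname read_eem
#' @param x An [eem()].
#' @export
write_eem <- function(x, path) {
  m <- eem_matrix(x)
  out <- rbind(c(NA, attr(x, "em_axis")),
               cbind(attr(x, "ex_axis"), unname(m)))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "")
  invisible(path)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  if (length(kv) == 0L) return(list())
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  vals <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) trimws(v) else n
  })
  stats::setNames(vals, trimws(keys))
}

write_header <- function(meta, path) {
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(sprintf("# %s=%s", names(meta),
                     vapply(meta, function(v) format(v, digits = 15),
                            character(1))),
             path)
}
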