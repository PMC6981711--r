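#' Compare binding constants with and without a site marker
#'
#' Site-marker displacement: the ligand's binding constant is re-measured in
#' the presence of a probe with a known albumin site. A drop signals
#' competition for (or negative cooperativity at) that site; a rise signals
#' an allosteric enhancement.
#'
#' @param kb_base Binding constant without marker, M^-1, positive.
#' @param kb_with_marker Binding constant with marker, M^-1, positive.
#' @param unchanged_band Half-width (percent) of the band treated as
#'   unchanged. Default 5.
#' @return A list with `percent_change` (100 * (with - base)/base) and
#'   `label` (`"enhancement"`, `"reduction"`, `"unchanged"`).
#' @examples
#' compare_site_marker(1.746e4, 2.454e4)  # +41% enhancement
#' @export
compare_site_marker <- function(kb_base, kb_with_marker, unchanged_band = 5) {
  stopifnot(kb_base > 0, kb_with_marker > 0)
  pct <- 100 * (kb_with_marker - kb_base) / kb_base
  label <- if (abs(pct) <= unchanged_band) "unchanged"
           else if (pct > 0) "enhancement" else "reduction"
  list(percent_change = pct, label = label)
}

#' Run the full binding analysis pipeline
#'
#' Orchestrates every analysis stage on a set of titration series (one per
#' temperature) and optional spectral inputs, producing the report tables of
#' a standard quenching study: Stern-Volmer constants per temperature,
#' biphasic detection and windowed modified Stern-Volmer fits, double-log
#' binding fits, van't Hoff thermodynamics with force classification, FRET
#' distances, synchronous-spectrum shift classification, CD helix content,
#' and site-marker displacement. Stages whose inputs are absent are skipped
#' with a warning rather than failing.
#'
#' @param titrations List of [titration_series()] (inner-filter corrected),
#'   one per temperature.
#' @param tau0 Fluorophore lifetime (s) for kq. Default `1e-8`.
#' @param windows Optional named list of concentration windows (mol/L) for
#'   the modified Stern-Volmer stage; `NULL` uses [detect_biphasic()]
#'   defaults.
#' @param donor_emission,acceptor_absorption Optional spectra for the FRET
#'   stage (see [fret_analysis()]).
#' @param fret_f0,fret_f Donor intensities without/with acceptor for the
#'   FRET efficiency; default the first titration's F0 and its intensity at
#'   the smallest nonzero concentration.
#' @param kappa_sq Orientation factor(s) for the FRET stage; both presets
#'   are evaluated by default.
#' @param eem_reference,eem_bound Optional [eem()]s for the synchronous
#'   stage (without / with ligand).
#' @param cd_spectrum Optional CD [spectrum()] (millidegrees).
#' @param cd_cp,cd_n_residues,cd_path_cm CD normalization parameters.
#' @param markers Optional tibble with columns `marker` and `kb` (M^-1):
#'   binding constants re-measured with each site marker present.
#' @param shift_tolerance Peak-shift tolerance (nm) for the synchronous
#'   stage.
#' @return An object of class `analysis_report`: a list of tibbles/blocks
#'   (`stern_volmer`, `biphasic`, `modified_sv`, `binding`, `thermo`,
#'   `fret`, `synchronous`, `cd`, `site_markers`, `provenance`).
#' @export
run_pipeline <- function(titrations,
                         tau0 = 1e-8,
                         windows = NULL,
                         donor_emission = NULL,
                         acceptor_absorption = NULL,
                         fret_f0 = NULL,
                         fret_f = NULL,
                         kappa_sq = c(static = 0.476, dynamic = 2 / 3),
                         eem_reference = NULL,
                         eem_bound = NULL,
                         cd_spectrum = NULL,
                         cd_cp = 4e-6,
                         cd_n_residues = 583,
                         cd_path_cm = 0.1,
                         markers = NULL,
                         shift_tolerance = 1) {
  stopifnot(length(titrations) >= 1)
  report <- list()

  # --- quenching fits per temperature -------------------------------------
  sv <- purrr::map(titrations, stern_volmer_fit, tau0 = tau0)
  report$stern_volmer <- purrr::map_dfr(sv, glance)

  bi <- detect_biphasic(titrations[[1]])
  report$biphasic <- tibble::tibble(
    is_biphasic = bi$is_biphasic, curvature = bi$curvature,
    t_statistic = bi$t_statistic)
  wins <- windows %||% bi$windows
  report$modified_sv <- purrr::map_dfr(names(wins), function(wn) {
    purrr::map_dfr(titrations, function(s) {
      g <- glance(modified_sv_fit(s, window = wins[[wn]]))
      dplyr::mutate(g, window = wn, .before = 1)
    })
  })

  hills <- purrr::map(titrations, hill_fit)
  report$binding <- purrr::map_dfr(hills, glance)

  report$mechanism <- classify_mechanism(unname(sv))

  # --- thermodynamics from Kb(T) ------------------------------------------
  kbt <- tibble::tibble(
    temperature = purrr::map_dbl(hills, "temperature"),
    k = purrr::map_dbl(hills, "kb"))
  if (length(unique(kbt$temperature)) >= 2L) {
    th <- binding_thermodynamics(kbt)
    report$thermo <- dplyr::mutate(
      th$delta_g_by_t,
      delta_h = th$delta_h, delta_s = th$delta_s,
      r_squared = th$r_squared, force_class = th$force_class)
  } else {
    rlang::warn("Thermodynamics stage skipped: need >= 2 temperatures.")
  }

  # --- FRET ----------------------------------------------------------------
  if (!is.null(donor_emission) && !is.null(acceptor_absorption)) {
    first <- titrations[[1]]
    f0 <- fret_f0 %||% titr_f0(first)
    f <- fret_f %||% first$intensity[first$conc > 0][1]
    report$fret <- purrr::map_dfr(seq_along(kappa_sq), function(i) {
      fr <- fret_analysis(donor_emission, acceptor_absorption, f0, f,
                          kappa_sq = kappa_sq[i])
      tibble::tibble(orientation = names(kappa_sq)[i] %||% "",
                     kappa_sq = kappa_sq[i], e = fr$e, j = fr$j,
                     r0_nm = fr$r0, r_nm = fr$r,
                     valid_range = fr$valid_range, proximity = fr$proximity)
    })
  } else {
    rlang::warn("FRET stage skipped: donor/acceptor spectra not provided.")
  }

  # --- synchronous fluorescence -------------------------------------------
  if (!is.null(eem_reference) && !is.null(eem_bound)) {
    report$synchronous <- purrr::map_dfr(c(15, 60), function(dl) {
      ref <- synchronous_spectrum(eem_reference, dl)
      prt <- synchronous_spectrum(eem_bound, dl)
      sh <- classify_shift(ref, prt, tolerance = shift_tolerance)
      tibble::tibble(delta_lambda = dl,
                     residue = if (dl == 15) "tyrosine" else "tryptophan",
                     peak_ref_nm = peak_wavelength(ref) + dl,
                     shift_nm = sh$delta, shift_label = sh$label)
    })
  } else {
    rlang::warn("Synchronous stage skipped: EEMs not provided.")
  }

  # --- circular dichroism --------------------------------------------------
  if (!is.null(cd_spectrum)) {
    cd <- helix_from_cd(cd_spectrum, cd_cp, cd_n_residues, cd_path_cm)
    report$cd <- tibble::tibble(mre_208 = cd$mre_208,
                                helix_percent = cd$helix_percent,
                                clamped = cd$clamped)
  } else {
    rlang::warn("CD stage skipped: spectrum not provided.")
  }

  # --- site-marker displacement -------------------------------------------
  if (!is.null(markers) && nrow(markers) > 0) {
    base_kb <- kbt$k[which.max(kbt$temperature)]
    report$site_markers <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
      cm <- compare_site_marker(base_kb, markers$kb[i])
      tibble::tibble(marker = markers$marker[i], kb = markers$kb[i],
                     kb_base = base_kb,
                     percent_change = cm$percent_change, label = cm$label)
    })
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("specbind")),
    n_series = length(titrations),
    temperatures = purrr::map_dbl(titrations, titr_temperature),
    tau0 = tau0,
    input_hash = rlang::hash(list(titrations, tau0, windows)))
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Binding analysis report ==\n\n-- Stern-Volmer --\n")
  print(x$stern_volmer)
  cat(sprintf("mechanism: %s; biphasic: %s\n",
              x$mechanism, x$biphasic$is_biphasic))
  cat("\n-- Modified Stern-Volmer --\n"); print(x$modified_sv)
  cat("\n-- Binding (double-log) --\n"); print(x$binding)
  if (!is.null(x$thermo)) { cat("\n-- Thermodynamics --\n"); print(x$thermo) }
  if (!is.null(x$fret)) { cat("\n-- FRET --\n"); print(x$fret) }
  if (!is.null(x$synchronous)) { cat("\n-- Synchronous --\n"); print(x$synchronous) }
  if (!is.null(x$cd)) { cat("\n-- CD --\n"); print(x$cd) }
  if (!is.null(x$site_markers)) { cat("\n-- Site markers --\n"); print(x$site_markers) }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Each table goes to `<dir>/<name>.tsv`; the whole report (including
#' provenance) additionally to `<dir>/report.json`.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param dir Output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      readr::write_tsv(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
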