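#' Configuration for the synthetic data generator
#'
#' Bundles the ground-truth parameters from which synthetic titrations,
#' spectra, EEMs and CD traces are generated. Defaults emulate a serum
#' albumin (4 uM, two tryptophans) titrated with a quinoline-type quencher:
#' a biphasic pair of site classes with quench constants of order 1e4 M^-1
#' referenced at 290 K that weaken as temperature rises, the instrument's
#' concentration ladder up to 80 uM, and 1% multiplicative intensity noise.
#'
#' @param sites Tibble with columns `ka` (M^-1 at `ref_temperature`) and
#'   `fa` (accessible fraction); `sum(fa)` must not exceed 1.
#' @param delta_h Effective van't Hoff enthalpy (J/mol) driving the
#'   temperature dependence of each site's quench constant. The default is
#'   negative: the quench constants weaken as temperature rises, the
#'   signature of static quenching.
#' @param delta_s Entropy term (J/(mol K)), used with `delta_h` when a site
#'   constant is generated absolutely rather than scaled (see
#'   [generate_titration()]).
#' @param f0 Unquenched fluorescence intensity, a.u.
#' @param conc Quencher concentration grid, mol/L, starting at 0.
#' @param temperatures Temperatures (K) at which series are generated.
#' @param ref_temperature Temperature (K) at which `sites$ka` is defined.
#' @param noise_sd Relative s.d. of multiplicative Gaussian intensity noise.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param model `"sites"` for the accessible-fraction forward model,
#'   `"hill"` for the double-logarithmic forward model (`hill_kb`,
#'   `hill_n`).
#' @param hill_kb,hill_n Ground truth for `model = "hill"` (Kb in M^-1 at
#'   `ref_temperature`, site count n).
#' @param eem_bands Tibble of separable EEM Gaussian bands: columns `ex0`,
#'   `em0` (centers, nm), `sx`, `sy` (s.d., nm), `amp`.
#' @param abs_protein,abs_ligand Tibbles of absorbance Gaussian bands
#'   (`center`, `width` s.d. nm, `amp` AU).
#' @param complex_shift,complex_gain Perturbation of the protein backbone
#'   band in the mixture spectrum: centre shift (nm) and amplitude factor.
#' @param cd_cp,cd_n_residues,cd_path_cm CD acquisition parameters: protein
#'   molar concentration, residue count, path length (cm).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    sites = tibble::tibble(ka = c(3.1419e4, 0.6e4), fa = c(0.6402, 0.3598)),
    delta_h = -38.5e3,
    delta_s = 0,
    f0 = 1000,
    conc = c(0, 1, 5, 10, 15, 20, 25, 30, 40, 50, 60, 70, 80) * 1e-6,
    temperatures = c(290, 300, 310),
    ref_temperature = 290,
    noise_sd = 0.01,
    seed = 1L,
    model = c("sites", "hill"),
    hill_kb = 1.7459e4,
    hill_n = 0.907,
    eem_bands = tibble::tibble(
      ex0 = c(280, 275, 230), em0 = c(341, 301, 342),
      sx = c(15, 30, 12), sy = c(22, 7, 22),
      amp = c(1, 0.45, 0.3)),
    abs_protein = tibble::tibble(center = c(222, 278),
                                 width = c(7, 12),
                                 amp = c(0.55, 0.28)),
    abs_ligand = tibble::tibble(center = c(207, 244),
                                width = c(6, 9),
                                amp = c(0.30, 0.20)),
    complex_shift = 2,
    complex_gain = 1.15,
    cd_cp = 4e-6,
    cd_n_residues = 583,
    cd_path_cm = 0.1) {
  model <- rlang::arg_match(model)
  stopifnot(noise_sd >= 0, f0 > 0, conc[1] == 0, !is.unsorted(conc),
            nrow(sites) >= 1, all(sites$ka >= 0), all(sites$fa > 0))
  if (sum(sites$fa) > 1 + 1e-12) {
    rlang::abort("Sum of accessible fractions exceeds 1.",
                 class = "specbind_config_error")
  }
  structure(
    list(sites = sites, delta_h = delta_h, delta_s = delta_s, f0 = f0,
         conc = conc, temperatures = temperatures,
         ref_temperature = ref_temperature, noise_sd = noise_sd,
         seed = as.integer(seed), model = model,
         hill_kb = hill_kb, hill_n = hill_n,
         eem_bands = eem_bands, abs_protein = abs_protein,
         abs_ligand = abs_ligand, complex_shift = complex_shift,
         complex_gain = complex_gain, cd_cp = cd_cp,
         cd_n_residues = cd_n_residues, cd_path_cm = cd_path_cm),
    class = "synthetic_config")
}

# site constant at temperature T, van't Hoff-scaled to the reference value
scale_k <- function(ka_ref, delta_h, t, t_ref) {
  ka_ref * exp(-delta_h / .R_GAS * (1 / t - 1 / t_ref))
}

#' Generate fluorescence titration series with known ground truth
#'
#' Forward model (default, `model = "sites"`): each site class i binds with
#' constant `K_i(T)` (the configured `ka` scaled across temperature through
#' the van't Hoff relation with the configured enthalpy) and removes its
#' accessible fraction of the signal at occupancy
#' `K_i [Q] / (1 + K_i [Q])`, so
#' `F = F0 (1 - sum_i fa_i K_i [Q] / (1 + K_i [Q]))`.
#' With `model = "hill"` the series follows
#' `(F0 - F)/F = Kb [Q]^n` instead. Multiplicative Gaussian noise of
#' relative s.d. `noise_sd` is applied to every intensity; generation is
#' deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A named list of [titration_series()], one per temperature
#'   (names `"T<K>"`).
#' @export
generate_titration <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    out <- lapply(config$temperatures, function(tt) {
      q <- config$conc
      if (config$model == "hill") {
        kb <- scale_k(config$hill_kb, config$delta_h, tt,
                      config$ref_temperature)
        ratio <- ifelse(q > 0, kb * q^config$hill_n, 0)
        f <- config$f0 / (1 + ratio)
      } else {
        occ <- rep(0, length(q))
        for (i in seq_len(nrow(config$sites))) {
          ki <- scale_k(config$sites$ka[i], config$delta_h, tt,
                        config$ref_temperature)
          occ <- occ + config$sites$fa[i] * ki * q / (1 + ki * q)
        }
        f <- config$f0 * (1 - occ)
      }
      if (config$noise_sd > 0) {
        f <- f * (1 + stats::rnorm(length(f), sd = config$noise_sd))
        f <- pmax(f, config$f0 * 1e-6)  # keep intensities positive
      }
      titration_series(q, f, temperature = tt)
    })
    stats::setNames(out, paste0("T", config$temperatures))
  })
}

gauss_band <- function(x, center, width, amp) {
  amp * exp(-(x - center)^2 / (2 * width^2))
}

#' Generate a synthetic excitation-emission matrix
#'
#' Sum of separable Gaussian excitation x emission bands (defaults: a
#' tryptophan-like band at 280/341 nm, a tyrosine-like band at 275/301 nm
#' and a weak backbone band at 230/342 nm), uniformly attenuated by the
#' fraction of fluorescence quenched at `ligand_conc` under the titration
#' model (first site-class set, reference temperature).
#'
#' @param config A [synthetic_config()].
#' @param ligand_conc Quencher concentration, mol/L. Default 0 (no ligand).
#' @param excitation,emission Axes, nm.
#' @return An [eem()]; intensities are nonnegative.
#' @export
generate_eem <- function(config, ligand_conc = 0,
                         excitation = seq(220, 320, by = 1),
                         emission = seq(285, 450, by = 1)) {
  stopifnot(inherits(config, "synthetic_config"), ligand_conc >= 0)
  b <- config$eem_bands
  m <- matrix(0, length(excitation), length(emission))
  for (i in seq_len(nrow(b))) {
    m <- m + outer(gauss_band(excitation, b$ex0[i], b$sx[i], b$amp[i]),
                   gauss_band(emission, b$em0[i], b$sy[i], 1))
  }
  occ <- 0
  if (ligand_conc > 0) {
    occ <- sum(config$sites$fa * config$sites$ka * ligand_conc /
                 (1 + config$sites$ka * ligand_conc))
  }
  eem(excitation, emission, m * (1 - occ))
}

#' Generate synthetic absorbance spectra (protein, ligand, mixture)
#'
#' Gaussian absorbance bands: protein at 222 nm (backbone) and 278 nm
#' (aromatics); ligand at 207 and 244 nm. The mixture is their sum with a
#' complexation perturbation of the backbone band (centre shifted by
#' `complex_shift` nm, amplitude multiplied by `complex_gain`), emulating
#' ground-state complex formation. Set `perturb = FALSE` for a strictly
#' additive mixture.
#'
#' @param config A [synthetic_config()].
#' @param wavelengths Grid in nm. Default 190-320 by 0.5.
#' @param perturb Apply the complexation perturbation? Default `TRUE`.
#' @return Named list of absorbance [spectrum()]s: `protein`, `ligand`,
#'   `mixture`.
#' @export
generate_absorbance <- function(config,
                                wavelengths = seq(190, 320, by = 0.5),
                                perturb = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  sum_bands <- function(bands) {
    Reduce(`+`, lapply(seq_len(nrow(bands)), function(i) {
      gauss_band(wavelengths, bands$center[i], bands$width[i], bands$amp[i])
    }))
  }
  protein <- sum_bands(config$abs_protein)
  ligand <- sum_bands(config$abs_ligand)
  pb <- config$abs_protein
  if (perturb) {
    backbone <- which.min(pb$center)
    pb$center[backbone] <- pb$center[backbone] + config$complex_shift
    pb$amp[backbone] <- pb$amp[backbone] * config$complex_gain
  }
  mixture <- sum_bands(pb) + ligand
  list(protein = spectrum(wavelengths, protein, "absorbance",
                          meta = list(label = "protein")),
       ligand = spectrum(wavelengths, ligand, "absorbance",
                         meta = list(label = "ligand")),
       mixture = spectrum(wavelengths, mixture, "absorbance",
                          meta = list(label = "protein+ligand")))
}

#' Generate a synthetic CD spectrum with prescribed helix content
#'
#' Builds a far-UV CD trace (200-260 nm) from two negative Gaussian bands at
#' 208 and 222 nm and rescales it so that the 208 nm ellipticity converts
#' (through the configured concentration, residue count and path length)
#' to exactly `MRE208 = -(helix_percent/100 * 29000 + 4000)`, i.e. the
#' requested alpha-helix percentage.
#'
#' @param helix_percent Target helix content, 0-100.
#' @param config A [synthetic_config()].
#' @param wavelengths Grid in nm; must include 208. Default 200-260 by 1.
#' @return A CD [spectrum()] in millidegrees.
#' @export
generate_cd <- function(helix_percent, config,
                        wavelengths = seq(200, 260, by = 1)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (helix_percent < 0 || helix_percent > 100) {
    rlang::abort("`helix_percent` must be in [0, 100].",
                 class = "specbind_config_error")
  }
  shape <- -(gauss_band(wavelengths, 208, 6, 1) +
               gauss_band(wavelengths, 222, 8, 0.95))
  i208 <- which.min(abs(wavelengths - 208))
  target_mre <- -(helix_percent / 100 * 29000 + 4000)
  target_theta <- target_mre *
    (10 * config$cd_cp * config$cd_n_residues * config$cd_path_cm)
  spectrum(wavelengths, shape * (target_theta / shape[i208]), kind = "cd",
           meta = list(cp = config$cd_cp, n_residues = config$cd_n_residues,
                       path_cm = config$cd_path_cm,
                       helix_percent_truth = helix_percent))
}
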