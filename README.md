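# specbind

Multi-spectroscopic analysis of small-molecule binding to fluorescent
proteins, built for the classic serum-albumin drug-binding workup: how
strongly does a drug bind plasma albumin, by what mechanism, at how many
sites, driven by which forces, and how close to the protein's tryptophans?
The package is aimed at biophysics and ADME groups who collect steady-state
fluorescence titrations, UV-Vis, synchronous/3D fluorescence and circular
dichroism spectra and want the full model chain in one scriptable, tested
place instead of a spreadsheet.

Every user-facing function takes a data frame and returns a tibble (or a
small result object with `tidy()`, `glance()` and `autoplot()` methods), so
analyses compose with the pipe.

## The models

With `F0`/`F` the donor fluorescence without/with quencher at concentration
`[Q]`, the package fits, by unweighted least squares on the customary
linearized forms:

- **Stern–Volmer**: `F0/F = 1 + Ksv [Q]`, with `kq = Ksv / τ0` (`τ0 = 1e-8 s`
  by default). `Ksv` falling with temperature and `kq >> 2e10 M⁻¹s⁻¹`
  classify the mechanism as static (ground-state complex).
- **Modified Stern–Volmer**: `F0/(F0−F) = 1/(fa·Ka·[Q]) + 1/fa`, giving the
  accessible fraction `fa` and effective constant `Ka`; concave-down
  curvature of this transform triggers biphasic low/high concentration
  windows (1–25 and 15–80 µM by default).
- **Double-logarithmic (Hill)**: `log10((F0−F)/F) = log10 Kb + n·log10 [Q]`
  for the binding constant and site count.
- **van't Hoff**: `ln K = −ΔH°/(RT) + ΔS°/R`, `ΔG° = ΔH° − TΔS°`, with the
  ΔH/ΔS sign table mapping to hydrophobic / H-bond–van der Waals /
  electrostatic driving forces.
- **FRET**: `E = (F0−F)/F0 = R0⁶/(R0⁶ + r⁶)`,
  `R0 = 0.211·(κ² n⁻⁴ φD J)^(1/6)` Å with
  `J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ` in M⁻¹cm⁻¹nm⁴.
- **CD helix content**: `MRE = θobs/(10·Cp·n·l)`,
  `helix% = 100·(−MRE208 − 4000)/29000`.
- Inner-filter correction `Fcor = Fobs·10^((Aex+Aem)/2)`, synchronous
  spectra at Δλ = 15/60 nm with red/blue shift classification,
  Savitzky–Golay second-derivative absorbance, and site-marker displacement
  arithmetic round out the pipeline.

A synthetic-data generator (`synthetic_config()`, `generate_titration()`,
`generate_eem()`, `generate_absorbance()`, `generate_cd()`) produces all of
these inputs with known ground truth, so the whole chain is testable
without instrument data.

## Worked example

```r
library(specbind)

# a noiseless synthetic titration with the default two-site ground truth
series <- generate_titration(synthetic_config(noise_sd = 0))
stern_volmer_fit(series$T290)
#> Stern-Volmer fit (T = 290 K, 12 points)
#>   Ksv = 1.672e+04 M^-1  kq = 1.672e+12 M^-1 s^-1  intercept = 1.048  r2 = 0.9970

modified_sv_fit(series$T290, window = c(1e-6, 25e-6))
#> Modified Stern-Volmer fit (T = 290 K, window 1e-06-2.5e-05 M, 6 points)
#>   Ka = 2.81e+04 M^-1  fa = 0.7919  r2 = 1.0000

# thermodynamics from measured binding constants at three temperatures
binding_thermodynamics(tibble::tibble(
  temperature = c(290, 300, 310),
  k = c(0.5506, 1.3590, 1.7459) * 1e4))
#> van't Hoff fit (3 temperatures)
#>   dH = 43.4 kJ/mol  dS = 222.0 J/(mol K)  r2 = 0.9146
#>   force class: hydrophobic
#>   dG (kJ/mol) at 290, 300, 310 K: -21.0, -23.2, -25.4

# distance between the drug and the protein's tryptophans
donor_acceptor_distance(0.19, 2.72)$r
#> [1] 3.463571

compare_site_marker(1.746e4, 2.454e4)
#> $percent_change 40.54983  $label "enhancement"
```

The apparent `Ksv` of 1.67e4 M⁻¹ reflects the mixed two-site default;
`kq ≈ 1.7e12 M⁻¹s⁻¹` is two orders above the collisional limit, marking
static quenching. Positive ΔH° and ΔS° with negative ΔG° indicate
spontaneous, hydrophobically driven binding; a FRET distance of 3.46 nm
puts the ligand within energy-transfer range of the tryptophans; a 41%
rise of `Kb` under warfarin indicates an allosteric enhancement rather
than site-I competition.

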