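---
title: "Models, conventions and design choices in specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind implements the standard steady-state spectroscopic workup of
protein–ligand binding: fluorescence-quenching model fits, thermodynamic
inference, FRET distance estimation, synchronous and second-derivative
spectral probes, circular-dichroism helix quantification, and site-marker
displacement. This vignette records the models and their assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical conventions — the things a maintainer or
reviewer would want written down.

## The quenching models and their assumptions

All binding information enters through a titration series: donor
fluorescence at one emission wavelength versus quencher concentration, at
one temperature, with the zero-concentration intensity defining `F0`.
Three linearized models are fitted by unweighted ordinary least squares:

* Stern–Volmer, `F0/F = 1 + Ksv[Q]`, valid for a single quenching
  population; its slope divided by the unquenched lifetime `τ0` gives the
  bimolecular rate constant `kq`. `τ0` defaults to `1e-8` s, the customary
  biopolymer value; it is a scale factor only.
* Modified Stern–Volmer, `F0/(F0−F) = 1/(fa·Ka·[Q]) + 1/fa`, which allows
  a fraction `1−fa` of fluorophores to be inaccessible. `fa` is reported
  as fitted, not clamped to `[0, 1]`: values slightly above 1 are a
  legitimate fit outcome on real data and truncating them would hide it.
* The double-logarithmic form `log10((F0−F)/F) = log10 Kb + n log10 [Q]`,
  whose slope estimates the number of equivalent sites.

All three share the assumptions of the underlying chemistry: free ligand
approximated by total ligand (the titration runs in large ligand excess
over the ~4 µM protein), intensities already corrected for the
inner-filter effect, and equilibrium at each point. We deliberately do
not refit the nonlinear forms or weight the regressions: the package's
goal is to reproduce the field's customary estimates, and weighted or
nonlinear variants give systematically different numbers.

Mechanism classification uses two signatures jointly: the temperature
trend of `Ksv` (strictly decreasing across temperatures → static,
strictly increasing → dynamic) and the magnitude of `kq` relative to the
diffusion-controlled collisional maximum of `2e10 M⁻¹s⁻¹`. An upward-curved
Stern–Volmer plot, flagged by the caller, classifies as mixed; anything
else is reported indeterminate rather than guessed.

### Biphasic detection

Two site classes occupied at different concentration regimes bend the
modified Stern–Volmer transform into a concave-down curve. Detection fits
a quadratic in `1/[Q]` and requires three things at once: a negative
quadratic coefficient, its t statistic beyond a threshold (default 2),
and a material bend — the quadratic contribution across the observed
range must exceed `1e-6` of the transform's range. The last guard exists
because on exactly linear data the quadratic coefficient of a
least-squares fit is pure floating-point noise, and a t statistic formed
from residuals of order `1e-12` can be arbitrarily large. When biphasic
behavior is detected the default analysis windows are 1–25 µM and
15–80 µM; they intentionally overlap, mirroring common practice of
anchoring both fits on the mid-range points.

## Thermodynamics

`vant_hoff_fit()` regresses `ln K` on `1/T` with `R = 8.314 J mol⁻¹ K⁻¹`
exactly; `ΔH° = −R·slope`, `ΔS° = R·intercept`. Two conventions for
`ΔG°` are exposed deliberately: `gibbs()` computes `ΔH° − TΔS°` from the
fit (the convention behind the published three-temperature tables this
package reproduces), while `gibbs_from_k()` computes `−RT ln K` from a
single constant. They agree exactly when `K(T)` lies on the van't Hoff
line and differ otherwise; reporting both makes the discrepancy visible
instead of silently choosing. Note that a binding series that *decreases*
with temperature forces a negative fitted `ΔH°`; published tables that
pair decreasing constants with positive enthalpies cannot be reproduced
under the van't Hoff relation, and the package makes no attempt to
"correct" either number. Energies are stored in J/mol; print methods
render kJ/mol to one decimal.

## FRET

The transfer efficiency comes from matched intensities,
`E = (F0−F)/F0`; the overlap integral is evaluated by the trapezoidal
rule on the common 0.5 nm grid of the overlap window (not 0–∞ — outside
the measured window both spectra are unknown, and the integrand is
negligible there for band-shaped spectra). With `J` in M⁻¹cm⁻¹nm⁴ the
prefactor convention `R0 = 0.211·(κ²n⁻⁴φD·J)^(1/6)` yields Ångström,
converted to nm on output; this is the only convention that lands
`R0 ≈ 2.7–2.9 nm` for `J ≈ 2e14` in the serum-albumin literature. Two κ²
presets are provided: 2/3 for freely tumbling dyes and 0.476 for static
random orientations — a ligand held in a protein pocket usually sits
between them, which is why the pipeline evaluates both. Defaults
`n = 1.336` and `φD = 0.15` are the customary values for tryptophan
donors in aqueous buffer. For reference inputs
(`E = 0.19`, `J = 2.19e14`), direct evaluation gives `R0 = 2.75/2.91` nm
for the two presets — about 1% above the widely quoted 2.72/2.88 nm,
consistent with `J` having been rounded to three digits after `R0` was
computed; the package reports its own evaluation and leaves the
reconciliation to the user. Distances carry two validity flags:
`0.5·R0 < r < 1.5·R0` (E is informative about r only near R0) and
`2 ≤ r ≤ 8` nm (the physical FRET window).

## Structural probes

Synchronous spectra are read off an excitation–emission matrix by
bilinear interpolation along `λem = λex + Δλ`, indexed by excitation
wavelength; Δλ = 15 nm isolates tyrosine-like signal and Δλ = 60 nm
tryptophan-like signal. Peak-shift classification uses a 1 nm tolerance
by default — instrument-resolution scale, since "no significant shift"
is the customary read-out — and labels positive shifts red (more polar
microenvironment) and negative ones blue (more hydrophobic).

CD helix content uses the mean residue ellipticity at 208 nm,
`MRE = θobs/(10·Cp·n·l)` with `Cp` in mol/L and `l` in cm. The
denominator form is fixed by dimensional analysis: only this reading
produces MRE magnitudes of order 1e4 compatible with the canonical
anchors of −33000 (pure helix) and −4000 (β/coil) at 208 nm. The raw
grid value at 208 nm is used without smoothing; percentages outside
0–100 are reported raw with a `clamped` flag rather than truncated.

## Inner-filter correction

The default is the standard base-10 form
`Fcor = Fobs·10^((Aex+Aem)/2)`, which assumes absorbances measured in a
1 cm cell with the fluorescence observed from the cell midpoint. A
natural-exponent variant is selectable (`convention = "exp_sum"`) because
some instrument software applies it; the two differ by ~15% at A = 0.3,
so the choice is explicit rather than buried.

## The synthetic generator

`synthetic_config()` fixes the study conditions: the concentration ladder
0–80 µM in the instrument's steps, temperatures 290/300/310 K, `F0`
normalized to 1000 a.u. (all models are scale-free), 1% multiplicative
Gaussian intensity noise (a mid-range figure for bench
spectrofluorometers; the generator takes any value), and a two-site
ground truth — a strong site (`Ka = 3.1419e4 M⁻¹`, `fa = 0.6402`) plus a
weak one (`0.6e4 M⁻¹`, `0.3598`) referenced at 290 K — whose constants
weaken with temperature through an effective van't Hoff enthalpy of
−38.5 kJ/mol, the signature of static quenching. A Hill-model forward
mode exists because site counts `n ≠ 1` are not representable in the
accessible-fraction model. EEM bands (tryptophan-like 280/341 nm,
tyrosine-like 275/301 nm, weak backbone 230/342 nm) were chosen so the
synchronous traces peak at the positions a serum-albumin instrument
records (301 and 341 nm); absorbance bands put the ligand at 207/244 nm
and the protein at 222/278 nm with an optional complexation perturbation
(+2 nm shift, ×1.15 gain of the backbone band); CD traces are rescaled so
the 208 nm ellipticity corresponds exactly to the requested helix
percentage. Seeds are explicit and generation is bit-reproducible.

What the generator does **not** emulate: wavelength-dependent detector
response, Rayleigh/Raman scatter ridges, baseline drift, photobleaching,
ligand depletion at low excess, and aggregation. Passing round-trip tests
therefore demonstrate correctness of the estimators under the stated
forward models, not robustness to every instrumental artifact of real
data.

### A caution on noisy linearized fits

The reciprocal and logarithmic transforms give the lowest-concentration
point extreme leverage: at 1 µM only a few percent of the signal is
quenched, so `F0−F` is a small difference of two large noisy numbers, and
that point sits at `1/[Q] = 1e6` — far from the mass of the regressor.
Simulation with the default generator shows the consequence: at 1%
intensity noise the modified Stern–Volmer `Ka` has a median relative
error near 100% across seeds (and ~12% even at 0.1% noise), while `Ksv`
and the double-log slope `n` stay within a few percent. Meanwhile the
fits' r² remains above 0.99, because the transformed response spans a
~25-fold range — a high r² on a linearized binding plot is **not**
evidence of a precise constant. This fragility is intrinsic to the
unweighted linearized estimator the field (and this package) uses;
practitioners wanting tight constants at realistic noise should average
replicate titrations or restrict fits away from the lowest
concentrations. The test suite asserts the tight recovery bounds only
where the estimator can deliver them.

## Degenerate inputs and tie-breaks

Titrations with no quenching return `Ksv = 0` with a `degenerate` flag
rather than an error; points with `F ≥ F0` (possible under noise) are
dropped with a warning before reciprocal/log transforms; `E = 0` returns
an infinite distance with a warning and `E = 1` returns zero. Peaks
within one grid step of a spectrum boundary are discarded as derivative
edge artifacts, and plateau maxima take their leftmost point. The
Savitzky–Golay second derivative uses a 21-point window of order 3 — the
nearest odd window to the 20-point smoothing settings quoted with
bench instruments, since symmetric filters need odd windows — on a
uniform grid (0.5 nm is the working resolution throughout), with
truncated-window edge handling flagged in the result metadata.

## Problem sizes

The shipped tests run 13-point titrations at three temperatures, 100-seed
replicate studies for the noise analyses, and spectra of a few hundred
points; the full suite completes in seconds on a laptop. These sizes were
chosen as the smallest that exercise every code path with comfortable
statistical resolution.

## Known limitations

No molecular docking, dynamic-light-scattering inversion, scatter-peak
handling in EEMs, secondary-structure deconvolution beyond the 208 nm
helix formula, time-resolved lifetime fitting, global multi-temperature
fitting, or quencher-depletion correction. These are out of scope by
design; the interfaces accept externally computed inputs where relevant
(e.g. any `Kb` pair for site-marker comparison).
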