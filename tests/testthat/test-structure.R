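test_that("synchronous spectra track the constant-offset diagonal", {
  ex <- seq(240, 320, 1); em <- seq(280, 420, 1)
  flat <- eem(ex, em, matrix(7, length(ex), length(em)))
  s <- synchronous_spectrum(flat, 60)
  expect_true(all(abs(s$value - 7) < 1e-12))
  expect_equal(spc_meta(s)$delta_lambda, 60)

  # single sharp band at (280, 340): diagonal maximum at ex = 280,
  # cross-checked against a brute-force scan over the grid
  band <- eem(ex, em, outer(exp(-(ex - 280)^2 / 18), exp(-(em - 340)^2 / 32)))
  s60 <- synchronous_spectrum(band, 60)
  brute <- vapply(ex, function(e) {
    exp(-(e - 280)^2 / 18) * exp(-(e + 60 - 340)^2 / 32)
  }, numeric(1))
  expect_equal(s60$value, brute, tolerance = 1e-10)
  expect_equal(peak_wavelength(s60), ex[which.max(brute)])

  # scaling the EEM scales the trace
  double <- eem(ex, em, 2 * eem_matrix(band))
  expect_equal(synchronous_spectrum(double, 60)$value, 2 * s60$value,
               tolerance = 1e-12)

  expect_error(synchronous_spectrum(band, 500),
               class = "specbind_range_error")
})

test_that("synthetic protein EEM shows tyrosine and tryptophan bands", {
  cfg <- synthetic_config()
  e <- generate_eem(cfg, excitation = seq(220, 320, 0.5),
                    emission = seq(285, 450, 0.5))
  tyr <- synchronous_spectrum(e, 15)
  trp <- synchronous_spectrum(e, 60)
  expect_equal(peak_wavelength(tyr) + 15, 301, tolerance = 1)
  expect_equal(peak_wavelength(trp) + 60, 341, tolerance = 1)
})

test_that("peak-shift classification is signed, tolerant and antisymmetric", {
  ref <- gaussian_spectrum(340, 15, grid = seq(290, 400, 0.5))
  expect_identical(classify_shift(ref, ref)$label, "none")

  red <- gaussian_spectrum(343, 15, grid = seq(290, 400, 0.5))
  blue <- gaussian_spectrum(337, 15, grid = seq(290, 400, 0.5))
  r <- classify_shift(ref, red, tolerance = 1)
  b <- classify_shift(ref, blue, tolerance = 1)
  expect_identical(r$label, "red"); expect_equal(r$delta, 3)
  expect_identical(b$label, "blue"); expect_equal(b$delta, -3)
  # swapping arguments flips the direction
  expect_identical(classify_shift(red, ref, tolerance = 1)$label, "blue")
  expect_identical(classify_shift(ref, red, tolerance = 5)$label, "none")

  mono <- spectrum(1:30, 1:30, kind = "fluorescence")
  expect_error(classify_shift(ref, mono), class = "specbind_analysis_error")
})

test_that("mean residue ellipticity normalizes the raw CD signal", {
  expect_equal(mean_residue_ellipticity(0, 4e-6, 583, 0.1), 0)
  expect_equal(round(mean_residue_ellipticity(-100, 4e-6, 583, 0.1)), -42882)
  m1 <- mean_residue_ellipticity(-50, 4e-6, 583, 0.1)
  expect_equal(mean_residue_ellipticity(-50, 4e-6, 583, 0.2), m1 / 2)
  expect_error(mean_residue_ellipticity(-50, 0, 583, 0.1),
               class = "specbind_precondition_error")
})

test_that("helix fraction is the affine map anchored at the canonical MREs", {
  expect_equal(helix_fraction(-33000)$helix_percent, 100)
  expect_equal(helix_fraction(-4000)$helix_percent, 0)
  expect_equal(helix_fraction(-25129.4)$helix_percent, 72.86, tolerance = 1e-3)
  # affine and strictly decreasing in MRE
  mres <- seq(-35000, 0, length.out = 20)
  pct <- vapply(mres, function(m) helix_fraction(m)$helix_percent, numeric(1))
  expect_true(all(diff(pct) < 0))
  expect_equal(diff(pct), rep(diff(pct)[1], length(pct) - 1),
               tolerance = 1e-9)
  # out-of-range values flagged, not clamped
  hot <- helix_fraction(-36000)
  expect_true(hot$clamped)
  expect_gt(hot$helix_percent, 100)
})

test_that("helix content can be read directly off a CD spectrum", {
  cfg <- synthetic_config()
  cd <- generate_cd(68.44, cfg)
  res <- helix_from_cd(cd, cfg$cd_cp, cfg$cd_n_residues, cfg$cd_path_cm)
  expect_equal(res$helix_percent, 68.44, tolerance = 0.01)
  fl <- gaussian_spectrum(340, 10)
  expect_error(helix_from_cd(fl, 4e-6, 583, 0.1),
               class = "specbind_type_error")
})
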