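test_that("generation is deterministic in the seed and validates config", {
  cfg <- synthetic_config(noise_sd = 0.01, seed = 7L)
  a <- generate_titration(cfg)
  b <- generate_titration(cfg)
  expect_identical(a, b)
  c <- generate_titration(synthetic_config(noise_sd = 0.01, seed = 8L))
  expect_false(identical(a, c))

  expect_error(
    synthetic_config(sites = tibble::tibble(ka = c(1e4, 1e4),
                                            fa = c(0.7, 0.6))),
    class = "specbind_config_error")
})

test_that("titration forward model honors its limiting cases", {
  # no binding: F stays at F0
  s0 <- single_site_series(0, 0.5)
  expect_true(all(s0$intensity == 1000))

  # positive binding, no noise: strictly decreasing intensity
  s <- generate_titration(synthetic_config(noise_sd = 0,
                                           temperatures = 290))[[1]]
  expect_true(all(diff(s$intensity) < 0))

  # quench constants follow the configured van't Hoff temperature trend
  cfg <- synthetic_config(noise_sd = 0)
  series <- generate_titration(cfg)
  kas <- vapply(series, function(x) {
    suppressWarnings(modified_sv_fit(x, window = c(1e-6, 25e-6)))$ka
  }, numeric(1))
  expect_true(all(diff(kas) < 0))  # negative enthalpy: weaker at higher T
})

test_that("two-site defaults reproduce the biphasic study picture", {
  s <- generate_titration(synthetic_config(noise_sd = 0,
                                           temperatures = 290))[[1]]
  res <- detect_biphasic(s)
  expect_true(res$is_biphasic)
  # the windowed effective constants bracket the two generating ones
  lo <- modified_sv_fit(s, window = res$windows$low)
  hi <- modified_sv_fit(s, window = res$windows$high)
  expect_gt(lo$ka, hi$ka)
  expect_lt(hi$ka, 3.1419e4)
  expect_gt(lo$ka, 0.6e4)
})

test_that("EEM generator places and attenuates the protein bands", {
  cfg <- synthetic_config()
  free <- generate_eem(cfg)
  m <- eem_matrix(free)
  idx <- which(m == max(m), arr.ind = TRUE)
  expect_equal(attr(free, "ex_axis")[idx[1]], 280, tolerance = 1)
  expect_equal(attr(free, "em_axis")[idx[2]], 341, tolerance = 1)
  expect_true(all(m >= 0))

  # saturating ligand with one fully accessible site: intensity scales by
  # the unbound fraction 1 - K q / (1 + K q)
  cfg1 <- synthetic_config(sites = tibble::tibble(ka = 5e4, fa = 1))
  qsat <- 80e-6
  bound <- generate_eem(cfg1, ligand_conc = qsat)
  occ <- 5e4 * qsat / (1 + 5e4 * qsat)
  expect_equal(max(eem_matrix(bound)), max(eem_matrix(generate_eem(cfg1))) *
                 (1 - occ), tolerance = 1e-9)

  dark <- synthetic_config(eem_bands = tibble::tibble(
    ex0 = 280, em0 = 340, sx = 10, sy = 10, amp = 0))
  expect_true(all(eem_matrix(generate_eem(dark)) == 0))
})

test_that("absorbance generator supports blank subtraction and derivatives", {
  cfg <- synthetic_config()
  plain <- generate_absorbance(cfg, perturb = FALSE)
  diff_spec <- subtract_blank(plain$mixture, plain$ligand)
  expect_equal(diff_spec$value, plain$protein$value, tolerance = 1e-12)

  pert <- generate_absorbance(cfg)
  rec <- subtract_blank(pert$mixture, pert$ligand)
  peaks <- find_peaks(rec, min_prominence = 0.05)
  # backbone band enhanced and shifted right by the complexation
  expect_equal(sort(peaks$wavelength), c(224, 278), tolerance = 0.5)

  d2 <- savgol_second_derivative(pert$ligand)
  minima <- find_peaks(d2, min_prominence = 0.05, direction = "min")
  expect_equal(sort(minima$wavelength), c(207, 244), tolerance = 1)
  d2p <- savgol_second_derivative(plain$protein)
  minp <- find_peaks(d2p, min_prominence = 0.05, direction = "min")
  expect_equal(sort(minp$wavelength), c(222, 278), tolerance = 1)
})

test_that("CD generator hits the requested helix content exactly", {
  cfg <- synthetic_config()
  for (h in c(0, 72.86, 100)) {
    cd <- generate_cd(h, cfg)
    out <- helix_from_cd(cd, cfg$cd_cp, cfg$cd_n_residues, cfg$cd_path_cm)
    expect_equal(out$helix_percent, h, tolerance = 0.01)
  }
  expect_equal(helix_from_cd(generate_cd(100, cfg), cfg$cd_cp,
                             cfg$cd_n_residues, cfg$cd_path_cm)$mre_208,
               -33000, tolerance = 0.5)
  expect_error(generate_cd(120, cfg), class = "specbind_config_error")
})
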