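test_that("Stern-Volmer fit recovers noiseless ground truth exactly", {
  q <- c(0, seq(1, 80, length.out = 10)) * 1e-6
  s <- titration_series(q, 1000 / (1 + 6.373e4 * q), temperature = 290)
  fit <- stern_volmer_fit(s, tau0 = 1e-8)
  expect_equal(fit$ksv, 6.373e4, tolerance = 1e-9)
  expect_equal(fit$kq, 6.373e12, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # kq = Ksv / tau0 holds exactly in the result object
  expect_identical(fit$kq, fit$ksv / fit$tau0)
})

test_that("Stern-Volmer fit flags unquenched data and rejects bad input", {
  q <- c(0, 1, 5, 10, 20) * 1e-6
  flat <- titration_series(q, rep(800, 5), temperature = 300)
  fit <- stern_volmer_fit(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$ksv, 0)
  expect_error(
    stern_volmer_fit(titration_series(c(0, 1e-6, 2e-6), c(10, 9, 8.5), 290)),
    class = "specbind_precondition_error")
})

test_that("modified Stern-Volmer fit recovers (Ka, fa) and respects windows", {
  s <- single_site_series(3.1419e4, 0.6402)
  fit <- modified_sv_fit(s)
  expect_equal(fit$ka, 3.1419e4, tolerance = 1e-9)
  expect_equal(fit$fa, 0.6402, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # fully accessible fluorophores: intercept of the transform is 1
  s1 <- single_site_series(5e4, 1)
  fit1 <- modified_sv_fit(s1)
  expect_equal(1 / fit1$fa, 1, tolerance = 1e-9)
  # and Ka then equals the Stern-Volmer constant
  expect_equal(fit1$ka, stern_volmer_fit(s1)$ksv, tolerance = 1e-6)

  win <- modified_sv_fit(s, window = c(1e-6, 25e-6))
  expect_equal(win$ka, 3.1419e4, tolerance = 1e-9)
  expect_lte(max(win$window), 25e-6)

  # F = F0 points are dropped with a warning; too few survivors error
  q <- c(0, 1, 5, 10, 20) * 1e-6
  s_eq <- titration_series(q, c(1000, 1000, 900, 800, 700), 290)
  expect_warning(modified_sv_fit(s_eq), "dropped")
  s_few <- titration_series(q[1:4], c(1000, 1000, 1000, 900), 290)
  expect_warning(expect_error(modified_sv_fit(s_few),
                              class = "specbind_fit_error"))
})

test_that("biphasic detection separates one- from two-site data", {
  one <- detect_biphasic(single_site_series(3.1419e4, 0.6402))
  expect_false(one$is_biphasic)
  expect_named(one$windows, "full")

  two <- generate_titration(synthetic_config(
    sites = tibble::tibble(ka = c(3e4, 0.6e4), fa = c(0.64, 0.36)),
    temperatures = 290, ref_temperature = 290, noise_sd = 0))[[1]]
  res <- detect_biphasic(two)
  expect_true(res$is_biphasic)
  expect_lt(res$curvature, 0)
  expect_equal(res$windows$low, c(1e-6, 25e-6))
  expect_equal(res$windows$high, c(15e-6, 80e-6))

  # windowed fits bracket the two generating constants
  fit_lo <- modified_sv_fit(two, window = res$windows$low)
  fit_hi <- modified_sv_fit(two, window = res$windows$high)
  expect_gt(fit_lo$ka, fit_hi$ka)
  expect_lt(fit_hi$ka, 3e4)
  expect_gt(fit_lo$ka, 0.6e4)

  few <- titration_series(c(0, 1, 5, 10) * 1e-6, c(1000, 950, 850, 760), 290)
  out <- detect_biphasic(few)
  expect_false(out$is_biphasic)
  expect_true(out$too_few_points)
})

test_that("double-log fit recovers (Kb, n) and slope 1 for 1:1 binding", {
  s <- hill_series(1.7459e4, 0.907)
  fit <- hill_fit(s)
  expect_equal(fit$kb, 1.7459e4, tolerance = 1e-9)
  expect_equal(fit$n, 0.907, tolerance = 1e-9)

  prop <- hill_series(2e4, 1)
  expect_equal(hill_fit(prop)$n, 1, tolerance = 1e-9)

  q <- c(0, 1, 5, 10, 20) * 1e-6
  s_eq <- titration_series(q, c(1000, 1001, 900, 800, 700), 290)
  expect_warning(hill_fit(s_eq), "dropped")
})

test_that("all three fits round-trip noiseless parameters below 1e-6", {
  cases <- list(list(ka = 6.373e4, fa = 1), list(ka = 5.415e4, fa = 1),
                list(ka = 3.1419e4, fa = 0.6402),
                list(ka = 0.787e4, fa = 0.9567))
  for (cs in cases) {
    s <- single_site_series(cs$ka, cs$fa)
    m <- modified_sv_fit(s)
    expect_lt(abs(m$ka / cs$ka - 1), 1e-6)
    expect_lt(abs(m$fa / cs$fa - 1), 1e-6)
    if (cs$fa == 1) {
      expect_lt(abs(stern_volmer_fit(s)$ksv / cs$ka - 1), 1e-6)
      expect_lt(abs(hill_fit(s)$kb / cs$ka - 1), 1e-6)
      expect_lt(abs(hill_fit(s)$n - 1), 1e-6)
    }
  }
})

test_that("noisy recovery of the well-conditioned parameters stays tight", {
  # 1% multiplicative noise, 40 seeds: slope-type parameters fitted on the
  # mildly transformed scales (F0/F, log-log) recover well
  ksv_err <- vapply(1:40, function(sd) {
    fit <- stern_volmer_fit(single_site_series(6.373e4, 1, noise_sd = 0.01,
                                               seed = sd))
    abs(fit$ksv / 6.373e4 - 1)
  }, numeric(1))
  expect_lt(median(ksv_err), 0.05)

  n_err <- vapply(1:40, function(sd) {
    fit <- suppressWarnings(hill_fit(hill_series(1.7459e4, 0.907,
                                                 noise_sd = 0.01, seed = sd)))
    abs(fit$n / 0.907 - 1)
  }, numeric(1))
  expect_lt(median(n_err), 0.05)
})

test_that("mechanism classification follows the temperature/kq rule table", {
  static_tbl <- tibble::tibble(temperature = c(290, 300, 310),
                               ksv = unname(ksv_ref),
                               kq = unname(ksv_ref) / 1e-8)
  expect_identical(classify_mechanism(static_tbl), "static")

  dynamic_tbl <- tibble::tibble(temperature = c(290, 300, 310),
                                ksv = c(1, 1.2, 1.5) * 1e2,
                                kq = c(1, 1.2, 1.5) * 1e9)
  expect_identical(classify_mechanism(dynamic_tbl), "dynamic")
  expect_identical(classify_mechanism(dynamic_tbl, curvature_flag = TRUE),
                   "mixed")
  # non-monotone or rule-violating patterns are indeterminate
  odd <- tibble::tibble(temperature = c(290, 300, 310),
                        ksv = c(2, 1, 3) * 1e4, kq = c(2, 1, 3) * 1e12)
  expect_identical(classify_mechanism(odd), "indeterminate")
  expect_warning(
    out <- classify_mechanism(static_tbl[1, ]),
    "2 temperatures")
  expect_identical(out, "indeterminate")

  # list-of-fits interface
  fits <- lapply(c(290, 300, 310), function(tt) {
    k <- ksv_ref[[as.character(tt)]]
    q <- c(0, seq(1, 80, length.out = 8)) * 1e-6
    stern_volmer_fit(titration_series(q, 1000 / (1 + k * q), tt))
  })
  expect_identical(classify_mechanism(fits), "static")
})
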