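test_that("resample interpolates linearly and preserves kind and metadata", {
  s <- spectrum(c(200, 300), c(0, 10), kind = "absorbance",
                meta = list(label = "x"))
  expect_equal(resample(s, 250)$value, 5)

  const <- spectrum(seq(300, 400, 10), rep(3.2, 11), kind = "fluorescence")
  out <- resample(const, seq(305, 395, 2.5))
  expect_true(all(out$value == 3.2))
  expect_identical(spc_kind(out), "fluorescence")

  expect_identical(spc_meta(resample(s, c(220, 260)))$label, "x")
  expect_error(resample(s, c(150, 250)), class = "specbind_range_error")
})

test_that("resampling a 1 nm Gaussian onto 0.5 nm tracks the analytic curve", {
  g <- gaussian_spectrum(340, 15, amp = 100, grid = seq(280, 400, 1))
  fine <- seq(281, 399, 0.5)
  out <- resample(g, fine)
  analytic <- 100 * exp(-(fine - 340)^2 / (2 * 15^2))
  expect_lt(max(abs(out$value - analytic)), 1e-3 * 100)
  # idempotent on its own grid
  expect_equal(resample(out, fine)$value, out$value)
})

test_that("Savitzky-Golay second derivative is exact on polynomials", {
  grid <- seq(200, 300, 0.5)
  lin <- spectrum(grid, 2 + 0.3 * grid, kind = "absorbance")
  expect_lt(max(abs(savgol_second_derivative(lin)$value)), 1e-10)

  quad <- spectrum(grid, 1.7 * grid^2, kind = "absorbance")
  d2 <- savgol_second_derivative(quad)
  interior <- d2$value[30:170]
  expect_equal(interior, rep(2 * 1.7, length(interior)), tolerance = 1e-8)
  expect_equal(spc_meta(d2)$derivative, 2)

  irregular <- spectrum(c(1, 2, 4, 8, 16, 32, 64), rnorm(7), kind = "cd")
  expect_error(savgol_second_derivative(irregular),
               class = "specbind_precondition_error")
  expect_error(savgol_second_derivative(quad, window_points = 20),
               class = "specbind_precondition_error")
})

test_that("Savitzky-Golay second derivative is a linear operator", {
  grid <- seq(200, 260, 0.5)
  s1 <- spectrum(grid, sin(grid / 7), kind = "absorbance")
  s2 <- spectrum(grid, exp(-(grid - 230)^2 / 50), kind = "absorbance")
  a <- 2.5; b <- -1.3
  lhs <- savgol_second_derivative(
    spectrum(grid, a * s1$value + b * s2$value, kind = "absorbance"))$value
  rhs <- a * savgol_second_derivative(s1)$value +
    b * savgol_second_derivative(s2)$value
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("blank subtraction recovers the sample signal", {
  s <- gaussian_spectrum(278, 12, amp = 0.3, grid = seq(230, 330, 0.5),
                         kind = "absorbance")
  expect_true(all(abs(subtract_blank(s, s)$value) < 1e-12))

  zero <- spectrum(seq(230, 330, 0.5), rep(0, 201), kind = "absorbance")
  expect_equal(subtract_blank(s, zero)$value, s$value)

  fl <- gaussian_spectrum(340, 20, kind = "fluorescence")
  expect_error(subtract_blank(s, fl), class = "specbind_type_error")

  far <- gaussian_spectrum(600, 5, kind = "absorbance",
                           grid = seq(580, 620, 1))
  expect_error(subtract_blank(s, far), class = "specbind_range_error")
})

test_that("peak finding locates band maxima and ignores edges", {
  g <- gaussian_spectrum(340, 18, amp = 50, grid = seq(285, 450, 1))
  p <- find_peaks(g)
  expect_equal(nrow(p), 1)
  expect_equal(p$wavelength, 340, tolerance = 1)

  mono <- spectrum(1:50, (1:50)^1.3, kind = "fluorescence")
  expect_equal(nrow(find_peaks(mono)), 0)

  # maximum sitting on the boundary is not a peak
  half <- spectrum(seq(340, 450, 1),
                   50 * exp(-(seq(340, 450, 1) - 340)^2 / 648),
                   kind = "fluorescence")
  expect_equal(nrow(find_peaks(half)), 0)

  expect_error(peak_wavelength(mono), class = "specbind_analysis_error")
})

test_that("constructors enforce the container invariants", {
  expect_error(spectrum(c(1, 2, 2), 1:3, "cd"), class = "specbind_grid_error")
  expect_error(spectrum(1:3, 1:2, "cd"), class = "specbind_length_error")
  expect_error(titration_series(c(1e-6, 2e-6), c(10, 9), 290),
               class = "specbind_data_error")
  expect_error(titration_series(c(0, 1e-6), c(10, -1), 290),
               class = "specbind_data_error")
  expect_error(eem(c(300, 280), 300:310, matrix(0, 2, 11)),
               class = "specbind_grid_error")
  e <- eem(c(280, 290), c(300, 310, 320), matrix(1:6, 2, 3))
  expect_equal(unname(eem_matrix(e)[2, 3]), 6)
})
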