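# Difference arithmetic, conversion-fraction estimation, radical removal,
# quantification, and axis alignment.

mk_spec <- function(y, axis = seq(2150, 4650, by = 1), freq = 9.369126) {
  epr_spectrum(axis, y, frequency_GHz = freq)
}

test_that("difference and scaled subtraction satisfy their exact identities", {
  axis <- seq(2150, 4650, by = 1)
  tmpl <- gaussian_derivative_line(axis, 3380, 150)
  bg <- mk_spec(0.3 + sin(axis / 400))
  light <- mk_spec(bg$intensity + tmpl)
  expect_equal(difference_spectrum(light, bg)$intensity, tmpl,
               tolerance = 1e-12)
  expect_equal(difference_spectrum(bg, bg)$intensity, rep(0, length(axis)))

  pure <- mk_spec(tmpl)
  b <- mk_spec(gaussian_derivative_line(axis, 3000, 90))
  a <- mk_spec(pure$intensity + 0.65 * b$intensity)
  expect_equal(scaled_subtract(a, b, 0.65)$intensity, pure$intensity,
               tolerance = 1e-12)
  expect_equal(scaled_subtract(a, b, 0)$intensity, a$intensity)
  expect_equal(max(abs(scaled_subtract(a, a, 1)$intensity)), 0)
  expect_warning(scaled_subtract(a, b, 1.7), "range")
})

test_that("mismatched axes are rejected unless aligned first", {
  a <- mk_spec(rnorm(100), axis = seq(1000, 1099, by = 1))
  b <- mk_spec(rnorm(100), axis = seq(1000.5, 1099.5, by = 1))
  expect_error(difference_spectrum(a, b), "align")
  ab <- align_spectra(list(a, b))
  expect_s3_class(difference_spectrum(ab[[1]], ab[[2]]), "epr_spectrum")
})

test_that("align_spectra interpolates onto the common axis correctly", {
  f <- function(x) 2 + 0.003 * x # linear: exact under linear interpolation
  a <- mk_spec(f(seq(1000, 1200, by = 1)), axis = seq(1000, 1200, by = 1))
  b <- mk_spec(f(seq(1000.5, 1200.5, by = 1)), axis = seq(1000.5, 1200.5, by = 1))
  al <- align_spectra(list(a, b))
  expect_equal(al[[1]]$field_G, al[[2]]$field_G)
  expect_equal(al[[2]]$intensity, f(al[[2]]$field_G), tolerance = 1e-10)
  # smooth nonlinear signal interpolates to small error
  g <- function(x) sin(x / 30)
  c1 <- mk_spec(g(seq(1000, 1200, by = 0.5)), axis = seq(1000, 1200, by = 0.5))
  c2 <- mk_spec(g(seq(1000.25, 1200.25, by = 0.5)),
                axis = seq(1000.25, 1200.25, by = 0.5))
  al2 <- align_spectra(list(c1, c2))
  expect_lt(max(abs(al2[[2]]$intensity - g(al2[[2]]$field_G))), 1e-4)
  # disjoint ranges error
  d <- mk_spec(rnorm(50), axis = seq(5000, 5049, by = 1))
  expect_error(align_spectra(list(a, d)), "disjoint")
  # identity when axes already equal
  expect_identical(align_spectra(list(a, a))[[1]]$intensity, a$intensity)
})

test_that("conversion-fraction estimation recovers constructed fractions exactly", {
  axis <- seq(2150, 4650, by = 1)
  st <- ml_stick_spectrum(c(250, 250, 250, 250), 1.98, 9.369126)
  ml <- broaden_sticks(st, axis, 20)$intensity
  d240 <- mk_spec(ml)
  d140 <- mk_spec(0.65 * ml)
  est <- estimate_conversion_fraction(d240, d140)
  expect_equal(est$fraction_lost, 0.35, tolerance = 1e-12)
  expect_lt(est$residual_rms, 1e-14)
  est0 <- estimate_conversion_fraction(d240, d240)
  expect_equal(est0$fraction_lost, 0, tolerance = 1e-12)
  # degenerate reference errors
  zero <- mk_spec(rep(0, length(axis)))
  expect_error(estimate_conversion_fraction(zero, d140), "degenerate")
})

test_that("the fraction estimator is unbiased and window-stable", {
  axis <- seq(2150, 4650, by = 1)
  ml <- broaden_sticks(ml_stick_spectrum(c(250, 250, 250, 250), 1.98,
                                         9.369126), axis, 20)$intensity
  ml <- ml / diff(range(ml))
  f <- 0.35
  # bias < 0.005 at SNR 200 over 100 draws
  set.seed(41)
  sd200 <- 1 / 200
  est <- replicate(100, {
    d240 <- mk_spec(ml + rnorm(length(axis), 0, sd200 * sqrt(2)))
    d140 <- mk_spec((1 - f) * ml + rnorm(length(axis), 0, sd200 * sqrt(2)))
    estimate_conversion_fraction(d240, d140)$fraction_lost
  })
  expect_lt(abs(mean(est) - f), 0.005)
  # noiseless window invariance: full window vs its low-field half
  d240 <- mk_spec(ml); d140 <- mk_spec((1 - f) * ml)
  full <- estimate_conversion_fraction(d240, d140, window = c(2400, 4400))
  half <- estimate_conversion_fraction(d240, d140, window = c(2400, 3250))
  expect_lt(abs(full$fraction_lost - half$fraction_lost), 0.02)
})

test_that("radical removal flattens an injected narrow line and keeps the rest", {
  axis <- seq(2150, 4650, by = 1)
  B_rad <- field_for_g(2.0046, 9.369126)
  rad <- generate_radical(2.0046, 8, 5, axis, 9.369126)$intensity
  spec <- mk_spec(0.2 + rad)
  win <- c(B_rad - 30, B_rad + 30)
  for (m in c("fit", "interpolate")) {
    out <- remove_radical(spec, win, method = m)
    idx <- which(axis >= win[1] & axis <= win[2])
    expect_lt(max(abs(out$intensity[idx] - 0.2)), 0.01 * 5) # <= 1% of line pp
    expect_equal(out$intensity[-idx], spec$intensity[-idx])
  }
  # no radical present: unchanged within numerical noise
  flat <- mk_spec(rep(0.2, length(axis)))
  out2 <- remove_radical(flat, win, method = "interpolate")
  expect_equal(out2$intensity, flat$intensity, tolerance = 1e-12)
  expect_warning(remove_radical(spec, c(2300, 4500)), "20%")
})

test_that("double integration recovers the closed-form Gaussian area", {
  axis <- seq(1000, 2000, by = 0.5)
  A <- 3; sigma <- 40; B0 <- 1500
  deriv <- -A * (axis - B0) / sigma^2 * exp(-(axis - B0)^2 / (2 * sigma^2))
  sp <- epr_spectrum(axis, deriv, 9.37)
  area <- double_integral(sp, c(1100, 1900))
  expect_equal(area, A * sigma * sqrt(2 * pi), tolerance = 0.005 * area)
  # linearity and the zero spectrum
  sp3 <- epr_spectrum(axis, 3 * deriv, 9.37)
  expect_equal(double_integral(sp3, c(1100, 1900)), 3 * area,
               tolerance = 1e-9 * area)
  expect_equal(double_integral(epr_spectrum(axis, rep(0, length(axis)), 9.37),
                               c(1100, 1900)), 0)
})

test_that("difference operations commute with scaling and addition", {
  set.seed(51)
  axis <- seq(1000, 1999, by = 1)
  y1 <- rnorm(1000); y2 <- rnorm(1000)
  a <- mk_spec(y1, axis); b <- mk_spec(y2, axis)
  c_ <- 2.7
  ca <- mk_spec(c_ * y1, axis); cb <- mk_spec(c_ * y2, axis)
  expect_equal(difference_spectrum(ca, cb)$intensity,
               c_ * difference_spectrum(a, b)$intensity, tolerance = 1e-12)
  expect_equal(scaled_subtract(ca, cb, 0.4)$intensity,
               c_ * scaled_subtract(a, b, 0.4)$intensity, tolerance = 1e-12)
})
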