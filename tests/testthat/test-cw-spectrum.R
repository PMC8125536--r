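# Effective g-values, resonance search, powder averaging, signal location.

test_that("effective_g and field_for_g are exact inverses and match closed forms", {
  expect_equal(effective_g(3347, 9.369115), 2.0000, tolerance = 1e-4)
  expect_equal(effective_g(1633, 9.369115), 4.0990, tolerance = 1e-3)
  B <- c(500, 1650, 3400)
  expect_equal(field_for_g(effective_g(B, 9.4), 9.4), B, tolerance = 1e-10)
  expect_error(effective_g(-10, 9.4), "positive")
})

test_that("Kramers-doublet effective g-values reproduce the closed-form limits", {
  # fully rhombic S = 5/2: isotropic middle doublet at 30/7
  s52 <- spin_system(5/2, g = 2.00, D_cm1 = 2, E_over_D = 1/3)
  mid <- doublet_effective_g(s52, 2)
  expect_equal(unname(mid), rep(30/7, 3), tolerance = 1e-3)
  expect_lt(max(mid) - min(mid), 0.01)
  outer_set <- sort(c(doublet_effective_g(s52, 1), doublet_effective_g(s52, 3)))
  expect_equal(unique(round(outer_set, 2)), c(0.61, 0.86, 9.68),
               tolerance = 0.01)
  # axial S = 3/2, +/-1/2 doublet: (4, 4, 2)
  s32 <- spin_system(3/2, g = 2.00, D_cm1 = 2)
  expect_equal(unname(doublet_effective_g(s32, 1)), c(4, 4, 2),
               tolerance = 1e-3)
  expect_error(doublet_effective_g(s32, 3), "doublet_index")
})

test_that("the axial limit of doublet g is approached as E/D -> 0", {
  for (r in c(0.02, 0.005)) {
    g <- doublet_effective_g(spin_system(3/2, g = 2, D_cm1 = 2, E_over_D = r), 1)
    expect_equal(unname(g), c(4, 4, 2), tolerance = 12 * r)
  }
})

test_that("resonance search honours the h nu matching contract", {
  # S = 1/2: single resonance at h nu/(g beta), refined below 1e-6 h nu
  sys <- spin_system(1/2, g = 2.00, temperature_K = Inf)
  ts <- resonance_search(sys, c(0, 0, 1), 9.369115, c(0, 5000))
  expect_equal(nrow(ts), 1L)
  B_expect <- 9.369115 * ORACLE$ghz_to_cm / (2.00 * ORACLE$beta_cmG)
  expect_equal(ts$resonance_field_G, B_expect, tolerance = 1e-6)
  # contract: |dE(B*) - h nu| <= 1e-6 h nu, via an independent rebuild
  H <- build_hamiltonian(sys, c(0, 0, ts$resonance_field_G))
  dE <- diff(eigensystem(H)$energies)
  nu <- 9.369115 * ORACLE$ghz_to_cm
  expect_lt(abs(dE - nu), 1e-6 * nu)
  # empty window is not an error
  none <- resonance_search(sys, c(0, 0, 1), 9.369115, c(100, 200))
  expect_equal(nrow(none), 0L)
})

test_that("axial S=3/2 in the high-D limit gives g ~ 2 parallel and g ~ 4 perpendicular", {
  sys <- spin_system(3/2, g = 2.00, D_cm1 = 2, temperature_K = 8)
  par <- resonance_search(sys, c(0, 0, 1), 9.369, c(500, 5000))
  par <- par[which.max(par$amplitude), ]
  expect_equal(effective_g(par$resonance_field_G, 9.369), 2.00,
               tolerance = 0.02)
  perp <- resonance_search(sys, c(1, 0, 0), 9.369, c(500, 5000))
  perp <- perp[which.max(perp$amplitude), ]
  expect_equal(effective_g(perp$resonance_field_G, 9.369), 4.00,
               tolerance = 0.03 * 4)
})

test_that("an isotropic S=1/2 powder spectrum is a single symmetric derivative line", {
  axis <- seq(3100, 3600, length.out = 1000)
  sys <- spin_system(1/2, g = 2.00, temperature_K = 8)
  ps <- powder_spectrum(sys, 9.369115, axis, n_orientations = 300,
                        linewidth_G = 15)
  ctr <- locate_signal_center(ps, c(3200, 3500))
  B_expect <- field_for_g(2.00, 9.369115)
  expect_lt(abs(ctr - B_expect), diff(axis[1:2]))
  # symmetry: y(ctr + d) = -y(ctr - d), sampled by interpolation
  d <- seq(2, 70, by = 2)
  left <- stats::approx(ps$field_G, ps$intensity, ctr - d)$y
  right <- stats::approx(ps$field_G, ps$intensity, ctr + d)$y
  expect_lt(max(abs(left + right)) / max(abs(left)), 0.02)
})

test_that("the orientation-grid average converges monotonically", {
  rms <- function(a, b) sqrt(mean((a$intensity - b$intensity)^2))
  # a wide, sharp-featured pattern converges monotonically under doubling
  axis <- seq(800, 4000, length.out = 600)
  sys <- spin_system(3/2, g = c(2.1, 2.0, 1.95), D_cm1 = 2, E_over_D = 0.15,
                     temperature_K = 8)
  sp <- lapply(c(200, 400, 800, 1600), function(n) {
    powder_spectrum(sys, 9.369, axis, n_orientations = n, linewidth_G = 60)
  })
  d <- c(rms(sp[[1]], sp[[2]]), rms(sp[[2]], sp[[3]]), rms(sp[[3]], sp[[4]]))
  expect_true(all(diff(d) < 0))

  # once converged, doubling changes a broad-line spectrum by < 1% RMS
  axis2 <- seq(400, 2900, length.out = 600)
  g41 <- g41_spin52(hyperfine = FALSE)
  a <- powder_spectrum(g41, 9.369115, axis2, n_orientations = 6000,
                       linewidth_G = 140)
  b <- powder_spectrum(g41, 9.369115, axis2, n_orientations = 12000,
                       linewidth_G = 140)
  expect_lt(rms(a, b) / diff(range(b$intensity)), 0.01)
})

test_that("the absorption integral is conserved under linewidth changes", {
  axis <- seq(2800, 3900, length.out = 1500)
  sys <- spin_system(1/2, g = 2.00, temperature_K = 8)
  areas <- vapply(c(20, 40, 80), function(lw) {
    ps <- powder_spectrum(sys, 9.369115, axis, n_orientations = 300,
                          linewidth_G = lw)
    double_integral(ps, c(2900, 3800))
  }, numeric(1))
  expect_lt(max(abs(areas / areas[1] - 1)), 0.005)
})

test_that("Boltzmann weighting behaves physically", {
  # for a D = 0.45 cm^-1 S = 5/2 system, the same orientation shows
  # intradoublet transitions out of the lowest (1,2) and middle (3,4)
  # doublets; cooling increases the relative weight of the lower doublet
  sys <- g41_spin52(hyperfine = FALSE)
  n <- c(0.55, 0.6, sqrt(1 - 0.55^2 - 0.6^2))
  ratio <- vapply(c(6, 30, Inf), function(T) {
    s <- sys; s$temperature_K <- T
    ts <- resonance_search(s, n, 9.369115, c(100, 6000))
    a12 <- ts$amplitude[ts$lower == 1 & ts$upper == 2]
    a34 <- ts$amplitude[ts$lower == 3 & ts$upper == 4]
    a12 / a34
  }, numeric(1))
  expect_gt(ratio[1], ratio[2])
  expect_gt(ratio[2], ratio[3])

  # a fixed transition's population-difference weight shrinks with T
  amp12 <- vapply(c(3, 8, 30), function(T) {
    s <- sys; s$temperature_K <- T
    ts <- resonance_search(s, n, 9.369115, c(100, 6000))
    ts$amplitude[ts$lower == 1 & ts$upper == 2]
  }, numeric(1))
  expect_true(all(diff(amp12) < 0))

  # as T -> infinity relative amplitudes become population-independent:
  # a very hot spectrum is proportional to the equal-population one
  axis <- seq(800, 4000, length.out = 500)
  hot <- sys; hot$temperature_K <- 1e6
  inf <- sys; inf$temperature_K <- Inf
  a <- powder_spectrum(hot, 9.369, axis, n_orientations = 200, linewidth_G = 80)
  b <- powder_spectrum(inf, 9.369, axis, n_orientations = 200, linewidth_G = 80)
  scale <- sum(a$intensity * b$intensity) / sum(b$intensity^2)
  expect_lt(sqrt(mean((a$intensity - scale * b$intensity)^2)) /
              diff(range(a$intensity)), 0.05)
})

test_that("spectra at nu and 2 nu with doubled fields are congruent for D = 0", {
  sys <- spin_system(1/2, g = c(2.2, 2.05, 1.9), temperature_K = Inf)
  ax1 <- seq(2800, 4000, length.out = 800)
  ax2 <- 2 * ax1
  # congruence is in scaled coordinates: the lineshape width scales along
  # with the field axis
  s1 <- powder_spectrum(sys, 9.369, ax1, n_orientations = 400, linewidth_G = 30)
  s2 <- powder_spectrum(sys, 2 * 9.369, ax2, n_orientations = 400,
                        linewidth_G = 60)
  y1 <- s1$intensity / max(abs(s1$intensity))
  y2 <- s2$intensity / max(abs(s2$intensity))
  expect_lt(sqrt(mean((y1 - y2)^2)), 0.02)
})

test_that("locate_signal_center finds zero crossings, including under noise", {
  axis <- seq(1000, 2300, by = 1)
  y <- gaussian_derivative_line(axis, 1650, 12) +
    0.5 * gaussian_derivative_line(axis, 2100, 10)
  sp <- epr_spectrum(axis, y, 9.37)
  expect_lt(abs(locate_signal_center(sp, c(1500, 1800)) - 1650), 1)
  expect_lt(abs(locate_signal_center(sp, c(2000, 2200)) - 2100), 1)
  expect_error(locate_signal_center(epr_spectrum(axis, rep(1, length(axis)), 9.37),
                                    c(1500, 1800)), "feature|crossing")

  # Monte Carlo: SNR 20 noise moves the located center by well under a step
  set.seed(21)
  clean <- gaussian_derivative_line(axis, 1650, 10)
  peak <- max(abs(clean))
  shifts <- replicate(100, {
    noisy <- epr_spectrum(axis, clean + rnorm(length(axis), 0, peak / 20), 9.37)
    locate_signal_center(noisy, c(1550, 1750)) - 1650
  })
  expect_lt(median(abs(shifts)), 0.5)
  expect_lt(stats::quantile(abs(shifts), 0.95), 2)
})

test_that("orientation grids are deterministic, normalized and octant-restricted", {
  g1 <- orientation_grid(300)
  g2 <- orientation_grid(300)
  expect_identical(g1, g2)
  expect_equal(sum(g1$weights), 1, tolerance = 1e-12)
  expect_true(all(g1$vectors >= 0))
  expect_equal(rowSums(g1$vectors^2), rep(1, nrow(g1$vectors)),
               tolerance = 1e-12)
  expect_error(orientation_grid(10), ">= 50")
})
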