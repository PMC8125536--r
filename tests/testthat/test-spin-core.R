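# Hamiltonian assembly, diagonalization, and zero-field level structure.

nu_cm_at <- function(GHz) GHz * ORACLE$ghz_to_cm

test_that("Hamiltonians are Hermitian for randomized valid systems", {
  set.seed(11)
  for (k in 1:20) {
    S <- sample(c(1/2, 3/2, 5/2), 1)
    nuc <- if (k %% 3 == 0) list(mn_nucleus(runif(3, 10, 300))) else list()
    sys <- spin_system(S, g = runif(3, 1.8, 2.3), D_cm1 = runif(1, -2, 2),
                       E_over_D = runif(1, 0, 1/3),
                       a_cubic_cm1 = runif(1, -0.05, 0.05), nuclei = nuc)
    H <- build_hamiltonian(sys, runif(3, -4000, 4000))
    expect_lte(max(abs(H - Conj(t(H)))), 1e-12 * max(abs(H)))
  }
})

test_that("S=3/2 axial zero-field splitting is 2D and the zero matrix is trivial", {
  H <- build_hamiltonian(spin_system(3/2, D_cm1 = 0.3), c(0, 0, 0))
  e <- sort(Re(diag(H)))
  expect_equal(diff(range(e)), 0.6, tolerance = 1e-12) # gap 2D
  expect_equal(length(unique(round(e, 10))), 2L)

  H0 <- build_hamiltonian(spin_system(5/2, g = 2), c(0, 0, 0))
  expect_equal(max(abs(H0)), 0)
})

test_that("S=1/2 Zeeman splitting reproduces the microwave quantum (unit round trip)", {
  nu <- nu_cm_at(9.369115)
  B <- nu / (2.00 * ORACLE$beta_cmG) # ~3347 G
  sys <- spin_system(1/2, g = 2.00)
  e <- eigensystem(build_hamiltonian(sys, c(0, 0, B)))$energies
  expect_equal(diff(e), nu, tolerance = 1e-10)
  # and at g = 2.0023 the field solving dE = h nu matches h nu/(g beta)
  g <- 2.0023
  Bg <- nu / (g * ORACLE$beta_cmG)
  eg <- eigensystem(build_hamiltonian(spin_system(1/2, g = g), c(0, 0, Bg)))$energies
  expect_equal(diff(eg) / nu, 1, tolerance = 1e-5)
})

test_that("Kramers degeneracy holds at zero field, with and without nuclei", {
  systems <- list(
    spin_system(3/2, g = c(2.1, 2.0, 1.9), D_cm1 = 0.7, E_over_D = 0.2),
    spin_system(5/2, g = 2, D_cm1 = 2, E_over_D = 1/3),
    # (two I = 5/2 nuclei keep the total angular momentum content
    # half-integer, so the degeneracy survives hyperfine coupling; a single
    # I = 5/2 nucleus would make it integer and lift the protection)
    spin_system(5/2, g = c(1.98, 2.16, 2.18), D_cm1 = 0.45, E_over_D = 0.25,
                nuclei = list(mn_nucleus(c(150, 200, 250)),
                              mn_nucleus(45.2)))
  )
  for (sys in systems) {
    e <- eigensystem(build_hamiltonian(sys, c(0, 0, 0)))$energies
    pairs <- matrix(e, nrow = 2)
    expect_lt(max(abs(pairs[2, ] - pairs[1, ])), 1e-10)
  }
})

test_that("the fine-structure part is traceless", {
  for (sys in list(spin_system(3/2, D_cm1 = 1.2, E_over_D = 0.1),
                   spin_system(5/2, D_cm1 = -0.8, E_over_D = 0.3,
                               a_cubic_cm1 = 0.04),
                   spin_system(5/2, D_cm1 = 0.45, E_over_D = 0.25,
                               nuclei = list(mn_nucleus(194.2))))) {
    H <- build_hamiltonian(sys, c(0, 0, 0))
    expect_lt(abs(sum(diag(H))), 1e-10)
  }
})

test_that("eigenvalue spectrum is covariant under axis permutations of tensors and field", {
  # permuting (x,y,z) -> (y,z,x) for g, A and the field leaves eigenvalues
  # unchanged (a 120-degree rotation; the cubic term is permutation-invariant)
  perm <- c(2, 3, 1)
  g <- c(2.18, 2.05, 1.95)
  A <- c(120, 180, 240)
  B <- c(800, -300, 2200)
  ev <- function(gv, Av, Bv) {
    sys <- spin_system(5/2, g = gv, a_cubic_cm1 = 0.03,
                       nuclei = list(mn_nucleus(Av)))
    sort(eigensystem(build_hamiltonian(sys, Bv))$energies)
  }
  expect_equal(ev(g, A, B), ev(g[perm], A[perm], B[perm]), tolerance = 1e-10)
})

test_that("eigensystem validates input and handles trivial matrices", {
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(eigensystem(bad), "Hermitian")
  triv <- eigensystem(matrix(0, 1, 1))
  expect_equal(triv$energies, 0)
  # ascending order and unitarity on a random Hermitian matrix
  set.seed(4)
  A <- matrix(complex(real = rnorm(36), imaginary = rnorm(36)), 6)
  es <- eigensystem((A + Conj(t(A))) / 2)
  expect_true(all(diff(es$energies) >= 0))
  U <- es$states
  expect_lt(max(abs(Conj(t(U)) %*% U - diag(6))), 1e-10)
})

test_that("invalid spin systems and unsupported features are rejected", {
  expect_error(spin_system(2, D_cm1 = 1), "one of")
  expect_error(spin_system(5/2, g = c(2, -2, 2)), "g-values")
  expect_error(nucleus(5/2, 100, quadrupole_P = 1), "quadrupole")
  expect_error(nucleus(0.4, 100), "half-integer")
})

test_that("ZFS canonicalization reorders any (D, E) into 0 <= E/D <= 1/3", {
  set.seed(7)
  for (k in 1:15) {
    D <- runif(1, -2, 2)
    r <- runif(1, -3, 3) # wildly out-of-convention rhombicity
    sys <- spin_system(5/2, g = runif(3, 1.9, 2.2), D_cm1 = D, E_over_D = r)
    expect_gte(rhombicity(sys), 0)
    expect_lte(rhombicity(sys), 1/3 + 1e-12)
    # the reordering is a relabelling: zero-field eigenvalues are unchanged
    expect_equal(oracle_zfs_eigvals(5/2, sys$D_cm1, sys$E_cm1),
                 oracle_zfs_eigvals(5/2, D, D * r), tolerance = 1e-10)
  }
})

test_that("zero-field doublet ladder matches closed forms and brute force", {
  # S = 3/2: gap is 2 sqrt(D^2 + 3 E^2)
  lv <- zero_field_levels(spin_system(3/2, D_cm1 = 0.45, E_over_D = 0.25))
  expect_equal(nrow(lv), 2L)
  expect_equal(lv$degeneracy, c(2L, 2L))
  D <- 0.45; E <- 0.45 * 0.25
  expect_equal(lv$energy_cm1[2], 2 * sqrt(D^2 + 3 * E^2), tolerance = 1e-10)

  # S = 5/2 rhombic: three doublets matching the brute-force 6x6
  sys <- spin_system(5/2, D_cm1 = 2, E_over_D = 1/3)
  lv5 <- zero_field_levels(sys)
  expect_equal(nrow(lv5), 3L)
  expect_equal(lv5$degeneracy, c(2L, 2L, 2L))
  ref <- oracle_zfs_eigvals(5/2, 2, 2/3)
  expect_equal(lv5$energy_cm1, unique(round(ref - min(ref), 10)),
               tolerance = 1e-8)

  # S = 1/2: single doublet, no gaps
  lv1 <- zero_field_levels(spin_system(1/2))
  expect_equal(lv1$energy_cm1, 0)
  expect_equal(lv1$degeneracy, 2L)
})

test_that("spin systems round-trip through the YAML config format", {
  sys <- spin_system(5/2, g = c(1.98, 2.16, 2.18), D_cm1 = 0.45,
                     E_over_D = 0.25,
                     nuclei = list(mn_nucleus(194.2), mn_nucleus(45.2)),
                     temperature_K = 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spin_system(sys, path)
  back <- read_spin_system(path)
  expect_equal(back$S, sys$S)
  expect_equal(back$g, sys$g, tolerance = 1e-10)
  expect_equal(back$D_cm1, sys$D_cm1, tolerance = 1e-10)
  expect_equal(rhombicity(back), rhombicity(sys), tolerance = 1e-10)
  expect_equal(length(back$nuclei), 2L)
  expect_equal(back$nuclei[[1]]$A_MHz, sys$nuclei[[1]]$A_MHz, tolerance = 1e-10)
})
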